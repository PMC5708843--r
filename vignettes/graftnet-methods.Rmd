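---
title: "Methods: the multiscale vein-graft adaptation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multiscale vein-graft adaptation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftnet)
```

## The biological problem

A vein transplanted into the arterial circulation must adapt to a pressure
and flow regime it was never built for. Part of that adaptation — wall
thickening with lumen expansion — is benign. Its pathological exaggeration,
*intimal hyperplasia*, narrows the lumen through smooth-muscle-cell (SMC)
proliferation and extracellular-matrix (ECM) deposition and is the dominant
cause of early graft failure. The driving stimulus in this model is
hemodynamic: wall shear stress below its arterial set point accelerates the
hyperplastic response, and a ligated (low-flow) graft is the canonical
pro-hyperplastic scenario.

`graftnet` implements a multiscale model of this process: gene-expression
dynamics (five clusters of co-expressed genes per biologic process) drive
cell and matrix kinetics, which drive wall morphology, which feeds back on
the shear stimulus. On top of the forward model sit a three-stage
genetic-algorithm (GA) calibration chain and an in-silico screening
procedure for constant gene-cluster therapies.

## Model structure

### Wall mechanics

The graft is a straight, circumferentially symmetric cylinder carrying
Poiseuille flow, so wall shear is

$$\tau = \frac{2\,\mu\,U_{\mathrm{eff}}}{R_1}, \qquad
U_{\mathrm{eff}} = f \cdot U,$$

with viscosity $\mu$ (cP), centerline velocity $U$ (m/s), lumen radius
$R_1$ (mm) and a dimensionless flow factor $f$ ($1$ = full flow, $0.1$ =
ligated side, a 90% flow reduction). With the default geometry
($\mu = 3.2$ cP, $U = 1$ m/s, $R_1 = 1$ mm) the arterial baseline is
$\tau_0 = 6.4$ Pa. Only shear *below* baseline stimulates growth:
$\Delta\tau^- = \min(\tau - \tau_0,\, 0)$.

The intima carries two area compartments, cellular ($A_{\mathrm{SMC}}$) and
matrix ($A_{\mathrm{ECM}}$), both in mm²:

$$\dot A_{\mathrm{SMC}} = -\alpha_1(t)\,\Delta\tau^-\,A_{\mathrm{SMC}},
\qquad
\dot A_{\mathrm{ECM}} = -\alpha_2(t)\,\Delta\tau^-\,A_{\mathrm{SMC}},$$

where the matrix derivative is floored at zero once $A_{\mathrm{ECM}}$ is
exhausted. Note that both derivatives are driven by $A_{\mathrm{SMC}}$, the
matrix one included: matrix deposition is modeled as proportional to the
available cellular machinery rather than to the matrix already in place.

Growth encroaches on the lumen with a fixed outer boundary:
$R_1(t) = \sqrt{R_{1,\mathrm{baseline}}^2 - \Delta A_{\mathrm{intima}}/\pi}$
(floored at 1 µm), shear is recomputed from $R_1(t)$ at every step, and the
loop closes: as the lumen narrows, shear rises back toward $\tau_0$ and
growth self-limits. Intimal thickness is reported as the encroachment depth
$R_{1,\mathrm{baseline}} - R_1(t)$; intimal area as
$A_{\mathrm{SMC}} + A_{\mathrm{ECM}}$. Both are emitted so either can serve
as a calibration target; thickness is the default.

### Cluster networks

Each biologic process (mitosis, apoptosis, ECM synthesis) has its own
network of the same five gene clusters, labeled A–E and mapped to indices
1–5. Cluster expression follows

$$\frac{dG_k}{dt} = \lambda(t) \sum_{j=1}^{5} A_{jk}\,(G_j - B_j),
\qquad
\lambda(t) = C_1 t^3 + C_2 t^2 + C_3 t + 1,$$

where $A_{jk}$ is the impact of cluster $j$ on cluster $k$, $B$ the
asymptote vector, and $\lambda(t)$ a cubic time-modulation mask that bends
the otherwise exponential dynamics into the observed single-peak,
late-asymptote curves. Time is measured in days everywhere (the 2 h sample
is $t = 1/12$ d), which fixes the units of $C_1, C_2, C_3$ as day⁻³,
day⁻², day⁻¹.

Because $\lambda$ only rescales time, the substitution
$s(t) = \int_0^t \lambda$ makes the system linear with constant
coefficients; its exact solution
$G(t) = B + e^{s(t) A^\top}(G_0 - B)$ (by eigen-expansion) is used
internally wherever many evaluations are needed (calibration objectives,
therapy grids). The public simulator integrates the ODE with an adaptive
stiff-safe method (lsoda, relative tolerance $10^{-8}$), and the test suite
pins the two routes together; the independent oracle for the linear case is
a matrix exponential computed by a third routine.

The initial condition $G_0$ is the earliest observed sample (2 h); no
pre-implant expression exists, so integration starts at $t = 0$ carrying
that value, which keeps $\alpha_1(t), \alpha_2(t)$ defined on the whole
follow-up for the coupling.

### Coupling

The constant growth coefficients of the plain wall model are replaced by
weighted, scaled combinations of the simulated cluster expressions:

$$\alpha_1(t) = \frac{1}{5}\sum_i \beta_{1i} w_{1i} G_i^{\mathrm{Mit}}(t)
             - \frac{1}{5}\sum_i \beta_{2i} w_{2i} G_i^{\mathrm{Apop}}(t),
\qquad
\alpha_2(t) = \frac{1}{5}\sum_i \beta_{3i} w_{3i} G_i^{\mathrm{ECM}}(t).$$

The signed weights $w$ (each in $[-1,1]$, $\sum_i |w_i| = 1$) express the
relative impact of each cluster on its biologic event — positive enhances,
negative inhibits. The scaling factors $\beta$ convert expression units into
area-growth-rate units (Pa⁻¹ day⁻¹ per unit expression). Negative net
$\alpha$ values (regression) are allowed; the floor on $A_{\mathrm{ECM}}$
and the multiplicative structure of the SMC equation keep areas
non-negative.

## Calibration chain

All three stages minimize sums of squared deviations with a real-coded GA
(tournament selection, blend crossover, Gaussian mutation with a linearly
decaying step, elitism). A naming quirk is worth recording: the stage
objectives are conventionally referred to as "RMS" deviations but are
implemented as plain sums of squared deviations, without the root — the
minimizer location is unchanged and the sum is cheaper inside a GA loop.

1. **Cluster-network stage** (33 unknowns per network: 25 in $A$, 5 in $B$,
   3 in $C$). Default bounds: $A_{jk} \in [-2, 2]$, $B$ inside the data
   range widened by one range-width on each side, $C_n \in [-1, 1]$. The
   objective carries a graded stability penalty — random interaction
   matrices are almost never stable, and the largest predicted exponent
   $\mathrm{Re}(\lambda_i)\,s(t)$ grades candidates *before* their
   trajectories overflow, which is what gives the GA a usable gradient
   toward the stable region. At every generation the best candidates are
   screened by silencing each cluster in turn: any knockdown that diverges
   or misfits the reference beyond the tolerance $Tol = 10$ (applied to the
   sum-of-squares of the four free clusters, over the six post-implant
   samples) disqualifies the candidate as a solution — it stays in the
   population, but cannot be returned.
2. **Weight stage** (5 unknowns per event). Candidates are projected onto
   the constraint set (clip to $[-1,1]$, rescale to $\sum|w| = 1$) before
   evaluation, so the GA itself is unconstrained and every returned vector
   satisfies the constraints exactly. The fit uses model-simulated cluster
   trajectories (the calibrated networks), keeping the chain closed; the
   event series is recorded at all seven sampling times including $t = 0$,
   and all seven are used.
3. **Scaling stage** (15 unknowns, bounds $[-10, 10]$). Every candidate
   requires a full coupled-model run; the cluster trajectories do not
   depend on $\beta$, so they are precomputed once on the integration grid
   and each candidate costs only the two-compartment wall integration,
   which is vectorized across the whole GA population. Fit quality is
   reported as the percentile root-mean-square deviation
   $\mathrm{PRMS} = 100\,\lVert I^{\mathrm{Ref}} - I^{\mathrm{Mod}}\rVert /
   \lVert I^{\mathrm{Ref}}\rVert$.

The GA restarts recursively: after each run the search box shrinks to a
fixed fraction of the previous width, centered on the incumbent best, and
the incumbent is injected into the restart population, so restarts can only
refine. Every stage takes an explicit seed, and the "run several times,
keep the least error" robustness protocol is exposed as `n_runs`
independently seeded runs with best-of selection (default 3).

### Numerical choices

* Cluster-network trajectories: exact eigen-expansion with an automatic
  fallback to lsoda when the eigenbasis is unreliable (defective matrices);
  divergence is flagged (bound: 50 × the maximum absolute reference value
  in screening contexts, $10^3$ otherwise), never raised as an error.
* Wall model: lsoda (rtol $10^{-8}$) for single runs; fixed-step RK4 at the
  dense output step (0.05 d) for population-vectorized evaluation. The two
  agree to $\sim 10^{-6}$ mm² on study-scale trajectories, far below both
  data noise and calibration residuals.
* Ties in therapy grid searches resolve to the smaller dose; the dose cap
  $\delta \le 3$ reflects the finite over-expression achievable in
  practice and is deliberately conservative.
* Degenerate inputs: all-zero weight vectors cannot be normalized and are
  rejected; an all-zero cluster trajectory set makes the weight stage
  meaningless and raises an error; occlusive growth floors the lumen radius
  at 1 µm and flags it.

## Gene-therapy screening

A therapy multiplies the initial expression of one or two clusters by a
constant $\delta \in [0, 3]$ and holds the treated cluster at that value for
the whole 28-day follow-up — in *all three* networks at once, because a
cluster is one gene set mapped into three biologic processes, and a real
intervention cannot silence it in one process only. Treated clusters still
drive the others through the coupling terms, which is what makes secondary
effects (and therapy failures) possible.

The score is the normalized reduction of 28-day intimal cross-sectional
area, $\mathrm{gain}\% = 100\,(A^{\mathrm{pre}} - A^{\mathrm{post}}) /
A^{\mathrm{pre}}$. A therapy is *viable* only if the weighted mitosis and
apoptosis combinations $\varphi_{\mathrm{Mit}}(t), \varphi_{\mathrm{Apop}}(t)$
stay non-negative throughout the treated simulation — the closest computable
reading of "cell mitosis and apoptosis must remain positive" in a model that
tracks areas rather than counts. Non-viable doses are excluded from the
optimization outright (under grid search the original algorithm's
"reinitiate at the last viable solution" penalty reduces to exclusion).

We search $\delta$ by exhaustive grid (step 0.01 for singles; a 0.05 coarse
grid plus 10× local refinement for pairs) rather than by GA: in one or two
dimensions the grid is deterministic, reproducible, and is its own oracle.
The ±50% sensitivity analysis probes a symmetric window around each optimal
dose (clipped to $[0,3]$) and summarizes robustness as the fraction of
viable probes retaining at least half the peak gain; a dose of zero has no
relative window and is reported without a robustness value.

## The synthetic-data generator

The generator defines the study conditions under which the package is
tested; it emulates the *design* of the animal experiment — not any
particular animal — and every choice below was fixed before the test suite
was written.

* **Sampling grid**: 0, 2 h, 1, 3, 7, 14, 28 days; ligated low-flow
  scenario ($f = 0.1$, $\tau_0 = 6.4$ Pa).
* **Expression curves**: each network's interaction matrix is drawn with
  one damped-oscillatory eigenpair (decay 0.08–0.35 day⁻¹, angular
  frequency 0.15–0.5 day⁻¹) plus three real decaying modes (0.1–2 day⁻¹),
  mixed by a near-identity orthogonal transform. This produces, by
  construction, the characteristic single early peak (the first-week
  inflammatory excitation) with a late asymptote, and moderate
  interconnectedness — strong enough that perturbing one cluster moves the
  others, weak enough that clamping one cluster does not destabilize the
  rest. Rejection sampling enforces the curve-shape contract (exactly one
  derivative sign change for at least three clusters, end-of-follow-up
  derivative below 10% of its peak, positive expression), mutual
  distinguishability of the five curves at the sampling grid (smallest
  singular value of the 7×5 design ≥ 0.02 — without this the event weights
  carry no recoverable signal), and all five knockdown-stability screens at
  $Tol = 10$.
* **Weights**: 3–4 enhancing clusters and at least one inhibiting cluster
  with $|w| \ge 0.12$ (after normalization), largest weight ≥ 0.25, and a
  baseline event rate bounded away from zero. Mixed signs are what make
  both inhibition-type and overexpression-type therapies available in the
  generated family, mirroring the heterogeneity of the real system.
* **Scaling**: $\beta$ directions follow the weight signs (so the
  event-level contributions are non-negative), with apoptosis at 0.3× and
  ECM at 0.5× the mitosis scale; the overall magnitude is solved (by root
  finding on the full coupled model) so the untreated 28-day intimal area
  is 2.0 mm² — strong but sub-occlusive hyperplasia for a 1 mm lumen with
  initial intimal areas $A_{\mathrm{SMC}} = 0.04$,
  $A_{\mathrm{ECM}} = 0.02$ mm².
* **Noise** (defaults 2%): multiplicative Gaussian on expression
  (microarray-like), additive Gaussian with s.d. relative to the series
  range on event rates and thickness.

What the generator does *not* emulate: per-gene structure within clusters,
animal-to-animal variability, paired high/low-flow grafts beyond the flow
factor, and measurement artifacts beyond Gaussian noise. Tests passing on
this family therefore demonstrate that the pipeline recovers models of this
structural class from data of this shape — not that the biological system
is identified. In particular the cluster-network stage is over-parameterized
(33 unknowns against 30 data values per network), so only trajectories, not
individual parameters, are recoverable, and the recovery tests are stated
at the trajectory level.

## Problem sizes used by the shipped tests and scripts

GA population sizing follows the 100-per-unknown rule at full scale; the
packaged test suite and the acceptance script run the chain at desk scale:
cluster-network stage with a 30× population (990), 80 generations, two
recursive restarts and a 15-generation stall stop; weight stage at the full
default population (500) with ten slow-annealing restarts (shrink 0.6) and
three seeded runs with best-of selection — the L1-normalized weight problem
has mirrored local basins, which the run-repetition protocol resolves by
objective, and its optima sit on constraint kinks, which the slow restart
cascade resolves to machine precision; scaling stage with the 100×
population (1500), 150 generations per run, ten recursive restarts at
shrink 0.5, a 25-generation stall stop, an early stop once PRMS falls
below 0.5%, and two seeded runs with best-of selection; one seeded run for
the other stages. Pair screening uses a 0.05–0.1 coarse
grid. The scaling stage needs the deep restart cascade because its
objective is a curved, strongly degenerate valley (the day-28 thickness
dominates); each restart shrinks the search box by a fixed factor, which is
what buys the final precision. These sizes keep a full chained run in the
minutes range on one core while leaving every qualitative conclusion of
the full-scale protocol intact; all of them are plain function arguments,
so a user can run the study-scale budgets unchanged.

## Known limitations

* The external radius and the pressures of the parent wall model are
  carried for fidelity but unused: the extracted subset is shear-only, with
  no tensile/pressure-driven medial dynamics and no pulsatility.
* Identifiability: thickness data constrain only low-dimensional
  functionals of $\beta$ (the model is deliberately over-parameterized), so
  calibrated $\beta$ values are not unique — a known scale degeneracy ties
  $\beta$ to the flow scale (doubling $U$ and halving $\beta$ is exact) —
  and therapy predictions from a calibrated model inherit whatever
  decomposition the fit happened to select.
* Therapies are constant-from-implantation only; late-onset or time-varying
  dosing is out of scope, as are simultaneous modulations of more than two
  clusters.
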