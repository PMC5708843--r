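# Synthetic study-shaped data with known ground truth.
#
# The generator emulates the study design rather than any particular animal:
# three five-cluster networks whose curves show the characteristic single
# early peak (the first-week inflammatory excitation) followed by a late
# asymptote; event rates that are exact signed-weight combinations of the
# cluster curves; and an intimal thickness course produced by the full
# coupled model under the ligated low-flow scenario.
#
# Study conditions baked into the defaults (see the methods vignette):
#   * interaction matrices drawn with one damped-oscillatory eigenpair plus
#     three real decaying modes - this produces the single-peak/asymptote
#     morphology by construction, and rejection sampling enforces it,
#   * mixed-sign weights (3-4 enhancing, at least one inhibiting cluster with
#     |w| >= 0.12), so both inhibition- and overexpression-type therapies
#     exist in the family of generated models,
#   * scaling factors calibrated so the untreated 28-day intimal area is
#     2 mm^2 (strong but sub-occlusive hyperplasia for a 1 mm lumen),
#   * 2% noise: multiplicative on expression (microarray-like), additive
#     (relative to the series range) on rates and thickness.

shape_ok <- function(traj, times) {
  if (!all(is.finite(traj)) || min(traj) <= 0.05) return(FALSE)
  d <- t(diff(t(traj)))  # 5 x (T-1) forward differences
  thr <- 1e-6 * max(abs(d))
  one_change <- vapply(seq_len(5), function(i) {
    s <- sign(d[i, abs(d[i, ]) > thr])
    sum(diff(s) != 0) == 1
  }, logical(1))
  if (sum(one_change) < 3) return(FALSE)
  # late asymptote: per-cluster end derivative below 10% of its own peak
  rate <- abs(d) / matrix(diff(times), 5, ncol(d), byrow = TRUE)
  all(rate[, ncol(rate)] < 0.1 * apply(rate, 1, max))
}

sample_cn <- function(grid, tol = 10, max_tries = 1000) {
  tt <- dense_times(grid)
  for (try in seq_len(max_tries)) {
    # wide eigenvalue spread: fast and slow decaying modes plus one damped
    # oscillation, so the five curves carry distinguishable temporal patterns
    a <- runif(1, 0.08, 0.35)
    b <- runif(1, 0.15, 0.5)
    reals <- -runif(3, 0.1, 2.0)
    D <- diag(c(0, 0, reals))
    D[1:2, 1:2] <- matrix(c(-a, -b, b, -a), 2, 2)
    # near-identity mixing: moderate interconnectedness, so that clamping a
    # single cluster perturbs - but does not destabilize - the others (the
    # study system admits viable therapies over wide modulation ranges)
    Q <- qr.Q(qr(diag(5) + 0.5 * matrix(rnorm(25), 5, 5)))
    Q <- Q %*% diag(sign(diag(Q)))
    Q <- Q[sample.int(5), , drop = FALSE]  # random clusters host the pair
    A <- t(Q %*% D %*% t(Q))
    B <- runif(5, 0.8, 1.6)
    G0 <- B + sample(c(-1, 1), 5, replace = TRUE) * runif(5, 0.25, 0.7)
    C <- c(runif(1, -1, 1) * 1e-5, runif(1, -1, 1) * 5e-4,
           runif(1, -1, 1) * 1e-2)
    if (min(eval_modulation(C, tt)) < 0.3) next
    params <- cn_parameters(A, B, C)
    traj <- cn_exact(params, G0, tt)
    if (is.null(traj) || !shape_ok(traj, tt)) next
    at_grid <- traj[, match(grid$times, tt), drop = FALSE]
    # the sampled curves must be mutually distinguishable (well-conditioned
    # design at the study grid), otherwise the event weights carry no signal
    if (min(svd(t(at_grid))$d) < 0.02) next
    ref <- cluster_series("MIT", at_grid, grid)  # tag irrelevant for screening
    stable <- all(vapply(cluster_labels(), function(cl) {
      knockdown_response(params, G0, cl, ref, tol = tol)$stable
    }, logical(1)))
    if (!stable) next
    return(list(params = params, G0 = G0, traj = traj, times = tt,
                at_grid = at_grid, tries = try))
  }
  stop("rejection budget exhausted while sampling a cluster network (",
       max_tries, " tries); relax the shape constraints or change the seed",
       call. = FALSE)
}

sample_weights <- function(net, G_grid, phi_floor = 0.1, max_tries = 500) {
  for (try in seq_len(max_tries)) {
    mags <- rexp(5) + 0.15
    n_neg <- sample(1:2, 1)
    signs <- rep(1, 5)
    signs[sample.int(5, n_neg)] <- -1
    w <- validate_weights(signs * mags)
    if (max(w) < 0.25 || min(w) > -0.12) next
    # the event rate must stay clearly positive at baseline (a rate series
    # hugging zero would make almost every perturbation non-viable)
    phi <- as.numeric(crossprod(G_grid, w))
    if (any(phi <= phi_floor)) next
    return(weight_vector(net, w))
  }
  stop("rejection budget exhausted while sampling weights", call. = FALSE)
}

#' Sample a ground-truth model
#'
#' Draws a complete, internally consistent model of the study system: three
#' knockdown-stable cluster networks with single-peak/late-asymptote
#' expression curves, mixed-sign event weights, and scaling factors
#' calibrated so the untreated model reaches a target 28-day intimal area.
#' All sampling is rejection-based under a seeded RNG, so the same seed
#' always yields the same truth.
#'
#' @param seed Integer seed.
#' @param grid A [time_grid()].
#' @param scenario A [vessel_state()] (default: ligated low-flow graft).
#' @param noise Named vector of noise magnitudes for [generate_dataset()]
#'   (`expression` multiplicative s.d., `rates` and `thickness` additive s.d.
#'   relative to the series range).
#' @param area28_target Untreated intimal area at the final follow-up time,
#'   mm^2.
#' @param max_tries Rejection budget per sampled component.
#' @return An object of class `ground_truth`: `cn`, `g0`, `weights` (per
#'   network MIT/APOP/ECM), `scaling`, `scenario`, `grid`, `noise`, `seed`.
#' @export
make_ground_truth <- function(seed, grid = time_grid(),
                              scenario = vessel_state(),
                              noise = c(expression = 0.02, rates = 0.02,
                                        thickness = 0.02),
                              area28_target = 2, max_tries = 500) {
  set.seed(seed)
  nets <- c(MIT = "MIT", APOP = "APOP", ECM = "ECM")
  cn <- lapply(nets, function(net) sample_cn(grid, max_tries = max_tries))
  repeat {
    weights <- lapply(nets, function(net) {
      sample_weights(net, cn[[net]]$at_grid, max_tries = max_tries)
    })
    # alpha1 must stay positive for the beta-direction choice below
    hgv <- (crossprod(cn$MIT$traj, abs(weights$MIT$w)) -
              0.3 * crossprod(cn$APOP$traj, abs(weights$APOP$w))) / 5
    if (all(hgv > 0)) break
  }
  g0 <- lapply(cn, function(x) x$G0)
  # beta = kappa * scale * sign(w): then beta*w = kappa * scale * |w| >= 0,
  # and the 28-day area is monotone in kappa -> solve for the target area.
  build_scaling <- function(kappa) {
    scaling_factors(kappa * sign(weights$MIT$w),
                    0.3 * kappa * sign(weights$APOP$w),
                    0.5 * kappa * sign(weights$ECM$w))
  }
  cnp <- lapply(cn, function(x) x$params)
  area_at <- function(kappa) {
    hp <- hybrid_parameters(cnp$MIT, cnp$APOP, cnp$ECM, unname(weights),
                            build_scaling(kappa), scenario, g0)
    sim <- simulate_hybrid(hp, NULL, grid, ds_method = "rk4")
    if (sim$diverged) return(NA_real_)
    m <- sim$morphology
    m$intimal_area[length(m$times)]
  }
  f <- function(lk) area_at(10^lk) - area28_target
  sol <- uniroot(f, c(-3, 3), tol = 1e-4)
  scaling <- build_scaling(10^sol$root)
  structure(list(cn = cnp, g0 = g0, weights = weights, scaling = scaling,
                 scenario = scenario, grid = grid, noise = noise,
                 seed = seed,
                 tries = vapply(cn, function(x) x$tries, numeric(1))),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> seed", x$seed, "- 3 cluster networks, weights:\n")
  for (net in names(x$weights)) {
    cat(sprintf("  %-4s %s\n", net,
                paste(sprintf("%+.3f", x$weights[[net]]$w), collapse = " ")))
  }
  invisible(x)
}

#' Hybrid parameter bundle of a ground truth
#'
#' @param truth A `ground_truth` object.
#' @return The corresponding [hybrid_parameters()] bundle.
#' @export
truth_parameters <- function(truth) {
  hybrid_parameters(truth$cn$MIT, truth$cn$APOP, truth$cn$ECM,
                    unname(truth$weights), truth$scaling, truth$scenario,
                    truth$g0)
}

#' Generate a study-shaped dataset from a ground truth
#'
#' Simulates the truth model, samples it at the study grid, and adds noise:
#' multiplicative Gaussian on cluster expression, additive Gaussian (s.d.
#' relative to the series range) on event rates and thickness. Event rates
#' are exact weighted combinations of the truth's cluster curves before the
#' noise is applied.
#'
#' @param truth A `ground_truth` from [make_ground_truth()].
#' @param noise Noise magnitudes (see [make_ground_truth()]); defaults to the
#'   truth's. Use zeros for a noise-free dataset.
#' @param seed Seed for the noise draws (default derived from the truth's).
#' @return An object of class `graft_dataset`: `clusters` (named list of
#'   three [cluster_series()]), `events` (a [cell_event_series()]),
#'   `thickness`, `grid`, plus the `noiseless` reference curves and the
#'   untreated `area28`.
#' @export
generate_dataset <- function(truth, noise = truth$noise,
                             seed = truth$seed + 1000L) {
  set.seed(seed)
  grid <- truth$grid
  hp <- truth_parameters(truth)
  sim <- simulate_hybrid(hp, NULL, grid)
  stopifnot(!sim$diverged)
  gidx <- match(grid$times, sim$phi$times)
  G_grid <- lapply(sim$cn, function(s) s$trajectories[, gidx, drop = FALSE])
  phi <- list(MIT = sim$phi$mit[gidx], APOP = sim$phi$apop[gidx],
              ECM = sim$phi$ecm[gidx])
  th <- sim$morphology$intimal_thickness[match(grid$times, sim$morphology$times)]
  nT <- length(grid$times)
  noisy_mult <- function(x, s) if (s > 0) x * (1 + rnorm(length(x), 0, s)) else x
  noisy_add <- function(x, s) {
    if (s > 0) x + rnorm(length(x), 0, s * max(diff(range(x)), 1e-12)) else x
  }
  clusters <- lapply(c(MIT = "MIT", APOP = "APOP", ECM = "ECM"), function(net) {
    cluster_series(net,
                   matrix(noisy_mult(G_grid[[net]], noise[["expression"]]),
                          5, nT, dimnames = list(cluster_labels(), NULL)),
                   grid)
  })
  events <- cell_event_series(noisy_add(phi$MIT, noise[["rates"]]),
                              noisy_add(phi$APOP, noise[["rates"]]),
                              noisy_add(phi$ECM, noise[["rates"]]), grid)
  thickness <- noisy_add(th, noise[["thickness"]])
  nend <- length(sim$morphology$times)
  structure(list(clusters = clusters, events = events, thickness = thickness,
                 grid = grid,
                 noiseless = list(clusters = G_grid, events = phi,
                                  thickness = th,
                                  area28 = sim$morphology$intimal_area[nend]),
                 seed = seed),
            class = "graft_dataset")
}

#' Write or read a dataset as delimited tables
#'
#' Writes the three cluster tables, the event-rate table and the thickness
#' table as CSV files (`clusters_mit.csv`, `clusters_apop.csv`,
#' `clusters_ecm.csv`, `events.csv`, `thickness.csv`) in `dir`, or reads them
#' back into a dataset list.
#'
#' @param dataset A `graft_dataset`.
#' @param dir Directory (created if needed).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()` the
#'   dataset list (without the `noiseless` reference, which is a property of
#'   the generator, not the files).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_timecourse_table(dataset$clusters$MIT, file.path(dir, "clusters_mit.csv"))
  write_timecourse_table(dataset$clusters$APOP, file.path(dir, "clusters_apop.csv"))
  write_timecourse_table(dataset$clusters$ECM, file.path(dir, "clusters_ecm.csv"))
  write_timecourse_table(dataset$events, file.path(dir, "events.csv"))
  write_timecourse_table(list(thickness = dataset$thickness,
                              grid = dataset$grid),
                         file.path(dir, "thickness.csv"))
  invisible(dir)
}

#' @rdname write_dataset
#' @param grid Optional [time_grid()] the tables must conform to.
#' @export
read_dataset <- function(dir, grid = NULL) {
  clusters <- list(
    MIT = read_timecourse_table(file.path(dir, "clusters_mit.csv"), "clusters",
                                network_id = "MIT", grid = grid),
    APOP = read_timecourse_table(file.path(dir, "clusters_apop.csv"), "clusters",
                                 network_id = "APOP", grid = grid),
    ECM = read_timecourse_table(file.path(dir, "clusters_ecm.csv"), "clusters",
                                network_id = "ECM", grid = grid))
  events <- read_timecourse_table(file.path(dir, "events.csv"), "events",
                                  grid = grid)
  th <- read_timecourse_table(file.path(dir, "thickness.csv"), "thickness",
                              grid = grid)
  structure(list(clusters = clusters, events = events,
                 thickness = th$thickness, grid = th$grid),
            class = "graft_dataset")
}
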