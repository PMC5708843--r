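# Coupling of the three cluster networks to the wall-growth system.
#
# The constant growth coefficients of the plain wall model are replaced by
# weighted, scaled combinations of the simulated cluster expressions:
#   alpha1(t) = sum_i beta1_i w1_i G_i^Mit(t)/5 - sum_i beta2_i w2_i G_i^Apop(t)/5
#   alpha2(t) = sum_i beta3_i w3_i G_i^ECM(t)/5
# so gene dynamics drive cell kinetics, which drive morphology, which feeds
# back on the shear stimulus.

#' Hybrid model parameter bundle
#'
#' Everything needed to run the coupled model: one calibrated cluster network
#' per cellular event, the three signed weight vectors, the 15 unit-scaling
#' factors, the vessel scenario, and the initial cluster expressions per
#' network.
#'
#' @param cn_mit,cn_apop,cn_ecm [cn_parameters()] for the mitosis, apoptosis
#'   and ECM networks.
#' @param weights List of three [weight_vector()]s (networks MIT, APOP, ECM in
#'   any order; matched by `network_id`).
#' @param scaling A [scaling_factors()] object.
#' @param scenario A [vessel_state()].
#' @param g0 Named list `MIT`, `APOP`, `ECM` of initial expressions (length 5
#'   each), by convention the earliest observed sample.
#' @return An object of class `hybrid_parameters`.
#' @export
hybrid_parameters <- function(cn_mit, cn_apop, cn_ecm, weights, scaling,
                              scenario, g0) {
  stopifnot(inherits(cn_mit, "cn_parameters"),
            inherits(cn_apop, "cn_parameters"),
            inherits(cn_ecm, "cn_parameters"),
            inherits(scaling, "scaling_factors"),
            inherits(scenario, "vessel_state"))
  ids <- vapply(weights, function(w) w$network_id, character(1))
  if (!setequal(ids, c("MIT", "APOP", "ECM"))) {
    stop("'weights' must contain one vector per network MIT/APOP/ECM",
         call. = FALSE)
  }
  weights <- setNames(weights, ids)[c("MIT", "APOP", "ECM")]
  if (!setequal(names(g0), c("MIT", "APOP", "ECM"))) {
    stop("'g0' must be a named list MIT/APOP/ECM", call. = FALSE)
  }
  g0 <- lapply(g0[c("MIT", "APOP", "ECM")], as.numeric)
  stopifnot(all(vapply(g0, length, 1L) == 5))
  structure(list(cn_mit = cn_mit, cn_apop = cn_apop, cn_ecm = cn_ecm,
                 weights = weights, scaling = scaling, scenario = scenario,
                 g0 = g0),
            class = "hybrid_parameters")
}

#' @export
print.hybrid_parameters <- function(x, ...) {
  cat("<hybrid_parameters> 3 cluster networks + weights + scaling;",
      sprintf("scenario: flow_factor = %g, tau0 = %g Pa\n",
              x$scenario$flow_factor, x$scenario$tau0))
  invisible(x)
}

check_alpha_range <- function(t, cn_results) {
  rng <- range(cn_results$MIT$times)
  if (any(t < rng[1] - 1e-9) || any(t > rng[2] + 1e-9)) {
    stop("time outside the simulated cluster-network range [",
         rng[1], ", ", rng[2], "]", call. = FALSE)
  }
}

#' Proliferation coefficient alpha1(t)
#'
#' The net proliferation coefficient of the coupled model: the scaled,
#' weighted mean of the mitosis-network cluster expressions minus the scaled,
#' weighted mean of the apoptosis-network expressions.
#'
#' @param t Time(s) in days, inside the simulated range.
#' @param params A [hybrid_parameters()] bundle.
#' @param cn_results Named list (`MIT`, `APOP`, `ECM`) of `cn_sim` results as
#'   returned by [simulate_network()].
#' @return `alpha1(t)`, vectorized over `t` (units Pa^-1 day^-1).
#' @export
alpha1 <- function(t, params, cn_results) {
  check_alpha_range(t, cn_results)
  gm <- cn_at(cn_results$MIT, t)   # 5 x length(t)
  ga <- cn_at(cn_results$APOP, t)
  b1w <- params$scaling$beta_mit * params$weights$MIT$w
  b2w <- params$scaling$beta_apop * params$weights$APOP$w
  as.numeric(crossprod(gm, b1w) / 5 - crossprod(ga, b2w) / 5)
}

#' Matrix-deposition coefficient alpha2(t)
#'
#' @inheritParams alpha1
#' @return `alpha2(t)`, the scaled weighted mean of the ECM-network cluster
#'   expressions, vectorized over `t`.
#' @export
alpha2 <- function(t, params, cn_results) {
  check_alpha_range(t, cn_results)
  ge <- cn_at(cn_results$ECM, t)
  b3w <- params$scaling$beta_ecm * params$weights$ECM$w
  as.numeric(crossprod(ge, b3w) / 5)
}

apply_therapy <- function(params, therapy) {
  if (is.null(therapy)) therapy <- therapy_spec()
  stopifnot(inherits(therapy, "therapy_spec"))
  frozen <- names(therapy$deltas)
  g0 <- params$g0
  if (length(frozen) > 0) {
    idx <- match(frozen, cluster_labels())
    for (net in names(g0)) g0[[net]][idx] <- therapy$deltas * g0[[net]][idx]
  }
  list(frozen = frozen, g0 = g0)
}

#' Simulate the coupled (hybrid) model
#'
#' Runs the three cluster networks (applying any therapy identically to the
#' treated cluster in all three networks: the cluster is one gene set mapped
#' into three biologic processes), forms the time-dependent coefficients
#' `alpha1(t)` and `alpha2(t)`, and integrates the shear-feedback wall model.
#'
#' @param params A [hybrid_parameters()] bundle.
#' @param therapy A [therapy_spec()] or `NULL` (untreated; identical to an
#'   empty spec).
#' @param grid A [time_grid()].
#' @param cn_method Cluster-network evaluation method, see
#'   [simulate_network()]. Default `"exact"` (the networks are linear in the
#'   reparameterized time, so the eigen-expansion is exact and fast).
#' @param ds_method Wall-model integrator, see [simulate_ds()].
#' @param divergence_bound Passed to [simulate_network()].
#' @return An object of class `hybrid_sim`: `morphology`
#'   (a `morphology_trajectory`), `cn` (list of the three `cn_sim`), `phi`
#'   (dense `phi_mit(t)`, `phi_apop(t)`, `phi_ecm(t)` weighted cluster
#'   combinations and their `times`), `alpha` (dense `alpha1`, `alpha2`), and
#'   `diverged`.
#' @export
simulate_hybrid <- function(params, therapy = NULL, grid,
                            cn_method = c("exact", "ode"),
                            ds_method = c("lsoda", "rk4"),
                            divergence_bound = 1e3) {
  cn_method <- match.arg(cn_method)
  ds_method <- match.arg(ds_method)
  th <- apply_therapy(params, therapy)
  cn <- list(
    MIT = simulate_network(params$cn_mit, th$g0$MIT, grid, frozen = th$frozen,
                           method = cn_method, divergence_bound = divergence_bound),
    APOP = simulate_network(params$cn_apop, th$g0$APOP, grid, frozen = th$frozen,
                            method = cn_method, divergence_bound = divergence_bound),
    ECM = simulate_network(params$cn_ecm, th$g0$ECM, grid, frozen = th$frozen,
                           method = cn_method, divergence_bound = divergence_bound))
  diverged <- any(vapply(cn, function(s) s$flags$diverged, logical(1)))
  tt <- cn$MIT$times
  if (diverged) {
    return(structure(list(morphology = NULL, cn = cn,
                          phi = NULL, alpha = NULL, diverged = TRUE),
                     class = "hybrid_sim"))
  }
  phi <- list(times = tt,
              mit = as.numeric(crossprod(cn$MIT$trajectories, params$weights$MIT$w)),
              apop = as.numeric(crossprod(cn$APOP$trajectories, params$weights$APOP$w)),
              ecm = as.numeric(crossprod(cn$ECM$trajectories, params$weights$ECM$w)))
  a1 <- alpha1(tt, params, cn)
  a2 <- alpha2(tt, params, cn)
  a1f <- approxfun(tt, a1, rule = 2)
  a2f <- approxfun(tt, a2, rule = 2)
  morph <- tryCatch(simulate_ds(a1f, a2f, params$scenario, grid,
                                method = ds_method),
                    error = function(e) NULL)
  structure(list(morphology = morph, cn = cn, phi = phi,
                 alpha = list(times = tt, alpha1 = a1, alpha2 = a2),
                 diverged = is.null(morph)),
            class = "hybrid_sim")
}

#' @export
print.hybrid_sim <- function(x, ...) {
  if (x$diverged) {
    cat("<hybrid_sim> DIVERGED\n")
  } else {
    n <- length(x$morphology$times)
    cat(sprintf("<hybrid_sim> 28-day intimal area %.4g mm^2, thickness %.4g mm\n",
                x$morphology$intimal_area[n], x$morphology$intimal_thickness[n]))
  }
  invisible(x)
}

#' Percentile root-mean-square deviation
#'
#' Normalized RMS distance between a reference and a model series, in
#' percent: `100 * sqrt(sum((ref - mod)^2)) / sqrt(sum(ref^2))`. This is the
#' quality score of the final thickness calibration (a value below 1 percent
#' indicates an excellent fit).
#'
#' @param reference,model Aligned numeric series.
#' @return PRMS in percent.
#' @examples
#' prms(1:5, 1.01 * (1:5)) # 1
#' @export
prms <- function(reference, model) {
  if (length(reference) != length(model)) {
    stop("series must be aligned (equal length)", call. = FALSE)
  }
  nrm <- sqrt(sum(reference^2))
  if (nrm == 0) stop("reference series has zero norm", call. = FALSE)
  100 * sqrt(sum((reference - model)^2)) / nrm
}
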