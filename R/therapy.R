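# In-silico gene therapy screening: constant single- or paired-cluster
# modulation (delta in [0, 3]) applied at implantation, scored by the
# normalized 28-day reduction of intimal cross-sectional area (gain%), under
# the biologic viability constraint that the weighted mitosis and apoptosis
# combinations stay non-negative throughout the follow-up.

gain_percent <- function(A_pre, A_post) 100 * (A_pre - A_post) / A_pre

VIABILITY_EPS <- -1e-9

#' Evaluate one gene therapy
#'
#' Runs the coupled model untreated and with the therapy applied (each treated
#' cluster starts at `delta` times its baseline expression and is held
#' constant in all three networks), and scores the normalized reduction of
#' 28-day intimal cross-sectional area,
#' `gain = 100 (A_pre - A_post) / A_pre` (percent). The therapy is viable only when
#' the weighted mitosis and apoptosis combinations remain non-negative over
#' the whole follow-up of the treated run; non-viable therapies carry no
#' gain value.
#'
#' @param model A calibrated [hybrid_parameters()] bundle.
#' @param spec A [therapy_spec()].
#' @param grid A [time_grid()].
#' @param pre Optional untreated `hybrid_sim` to reuse across evaluations.
#' @param ds_method Wall-model integrator (see [simulate_ds()]).
#' @return An object of class `therapy_outcome`: `spec`, `gain_percent`
#'   (`NA` when not viable), `A_pre`, `A_post` (mm^2 at the final time),
#'   `viable`, `diverged`, and `trajectories` (list `pre`, `post` of
#'   `hybrid_sim`).
#' @export
evaluate_therapy <- function(model, spec, grid, pre = NULL,
                             ds_method = c("lsoda", "rk4")) {
  ds_method <- match.arg(ds_method)
  stopifnot(inherits(spec, "therapy_spec"))
  if (is.null(pre)) {
    pre <- simulate_hybrid(model, NULL, grid, ds_method = ds_method)
  }
  post <- simulate_hybrid(model, spec, grid, ds_method = ds_method)
  diverged <- pre$diverged || post$diverged
  if (diverged) {
    return(structure(list(spec = spec, gain_percent = NA_real_,
                          A_pre = NA_real_, A_post = NA_real_,
                          viable = FALSE, diverged = TRUE,
                          trajectories = list(pre = pre, post = post)),
                     class = "therapy_outcome"))
  }
  viable <- all(post$phi$mit >= VIABILITY_EPS) &&
    all(post$phi$apop >= VIABILITY_EPS)
  n <- length(pre$morphology$times)
  A_pre <- pre$morphology$intimal_area[n]
  A_post <- post$morphology$intimal_area[n]
  structure(list(spec = spec,
                 gain_percent = if (viable) gain_percent(A_pre, A_post) else NA_real_,
                 A_pre = A_pre, A_post = A_post, viable = viable,
                 diverged = FALSE,
                 trajectories = list(pre = pre, post = post)),
            class = "therapy_outcome")
}

#' @export
print.therapy_outcome <- function(x, ...) {
  print(x$spec)
  if (x$diverged) {
    cat("  diverged simulation\n")
  } else if (!x$viable) {
    cat("  NOT viable (negative mitosis/apoptosis combination)\n")
  } else {
    cat(sprintf("  gain = %.2f%%  (area %.4g -> %.4g mm^2 at follow-up end)\n",
                x$gain_percent, x$A_pre, x$A_post))
  }
  invisible(x)
}

# Batch evaluation over a grid of modulation factors.  `deltas` is a matrix
# with one column per treated cluster; returns area at follow-up end,
# viability and divergence per row.  Cluster-network trajectories are
# evaluated exactly on the RK4 half-step grid; the wall model is integrated
# for all rows at once.
therapy_grid_eval <- function(model, clusters, deltas, grid) {
  deltas <- as.matrix(deltas)
  P <- nrow(deltas)
  idx <- match(clusters, cluster_labels())
  stopifnot(!anyNA(idx), length(idx) == ncol(deltas))
  times <- dense_times(grid)
  hg <- half_grid(times)
  nets <- list(MIT = model$cn_mit, APOP = model$cn_apop, ECM = model$cn_ecm)
  b1w <- model$scaling$beta_mit * model$weights$MIT$w
  b2w <- model$scaling$beta_apop * model$weights$APOP$w
  b3w <- model$scaling$beta_ecm * model$weights$ECM$w
  a1h <- matrix(0, length(hg), P)
  a2h <- matrix(0, length(hg), P)
  viable <- rep(TRUE, P)
  diverged <- rep(FALSE, P)
  bound <- 1e3
  for (r in seq_len(P)) {
    G <- vector("list", 3)
    names(G) <- names(nets)
    for (net in names(nets)) {
      g0 <- model$g0[[net]]
      g0[idx] <- deltas[r, ] * g0[idx]
      Gn <- cn_exact(nets[[net]], g0, hg, frozen = idx)
      if (is.null(Gn)) Gn <- cn_ode(nets[[net]], g0, hg, frozen = idx)
      if (is.null(Gn) || !all(is.finite(Gn)) || max(abs(Gn)) > bound) {
        diverged[r] <- TRUE
        break
      }
      G[[net]] <- Gn
    }
    if (diverged[r]) { viable[r] <- FALSE; next }
    phi_mit <- as.numeric(crossprod(G$MIT, model$weights$MIT$w))
    phi_apop <- as.numeric(crossprod(G$APOP, model$weights$APOP$w))
    viable[r] <- all(phi_mit >= VIABILITY_EPS) && all(phi_apop >= VIABILITY_EPS)
    a1h[, r] <- (crossprod(G$MIT, b1w) - crossprod(G$APOP, b2w)) / 5
    a2h[, r] <- crossprod(G$ECM, b3w) / 5
  }
  res <- ds_rk4_batch(a1h, a2h, model$scenario, times,
                      record_idx = length(times))
  area <- as.numeric(res$A_SMC[1, ] + res$A_ECM[1, ])
  area[diverged] <- NA_real_
  data.frame(deltas, area = area, viable = viable, diverged = diverged)
}

best_viable_row <- function(tab) {
  ok <- which(tab$viable & !tab$diverged & is.finite(tab$area))
  if (length(ok) == 0) return(NA_integer_)
  # ties resolved toward the earlier (smaller delta) row
  ok[which.min(tab$area[ok])]
}

#' Optimal single-cluster modulation
#'
#' Exhaustive search of the constant modulation factor `delta` in `[0, 3]`
#' (dense grid) minimizing the 28-day intimal area, excluding non-viable
#' modulations. Ties resolve to the smaller `delta`. Grid search is
#' deterministic and is its own oracle (a finer grid can only move the
#' optimum by less than one step).
#'
#' @param model A calibrated [hybrid_parameters()] bundle.
#' @param cluster Cluster label `"A"`..`"E"`.
#' @param grid A [time_grid()].
#' @param step Grid step for `delta` (default 0.01).
#' @return List with `delta_min`, `outcome` (a full [evaluate_therapy()]
#'   result at the optimum; `NULL` when no viable modulation exists),
#'   `viable_found`, and `table` (the full grid with areas and viability).
#' @export
optimize_single <- function(model, cluster, grid, step = 0.01) {
  dd <- seq(0, 3, by = step)
  tab <- therapy_grid_eval(model, cluster, matrix(dd, ncol = 1), grid)
  names(tab)[1] <- "delta"
  i <- best_viable_row(tab)
  if (is.na(i)) {
    warning("no viable modulation for cluster ", cluster, call. = FALSE)
    return(list(delta_min = NA_real_, outcome = NULL, viable_found = FALSE,
                table = tab))
  }
  delta_min <- tab$delta[i]
  outcome <- evaluate_therapy(model, therapy_spec(setNames(delta_min, cluster)),
                              grid)
  list(delta_min = delta_min, outcome = outcome, viable_found = TRUE,
       table = tab)
}

#' Optimal coupled (two-cluster) modulation
#'
#' Searches the `[0, 3]^2` square of simultaneous constant modulations of two
#' clusters: a coarse exhaustive grid followed by a local refinement around
#' the coarse optimum (one coarse cell, at a 10x finer step).
#'
#' @param model A calibrated [hybrid_parameters()] bundle.
#' @param clusters Two cluster labels.
#' @param grid A [time_grid()].
#' @param coarse Coarse grid step (default 0.05).
#' @param refine Whether to refine locally around the coarse optimum.
#' @return List with `deltas` (named optimum pair), `outcome`,
#'   `viable_found`, and `coarse_table`.
#' @export
optimize_pair <- function(model, clusters, grid, coarse = 0.05, refine = TRUE) {
  stopifnot(length(clusters) == 2, !anyDuplicated(clusters))
  dd <- seq(0, 3, by = coarse)
  combos <- as.matrix(expand.grid(d1 = dd, d2 = dd))
  tab <- therapy_grid_eval(model, clusters, combos, grid)
  i <- best_viable_row(tab)
  if (is.na(i)) {
    warning("no viable coupled modulation for ", paste(clusters, collapse = "+"),
            call. = FALSE)
    return(list(deltas = c(NA_real_, NA_real_), outcome = NULL,
                viable_found = FALSE, coarse_table = tab))
  }
  best <- as.numeric(combos[i, ])
  if (refine) {
    fine <- coarse / 10
    s1 <- seq(max(0, best[1] - coarse), min(3, best[1] + coarse), by = fine)
    s2 <- seq(max(0, best[2] - coarse), min(3, best[2] + coarse), by = fine)
    combos2 <- as.matrix(expand.grid(d1 = s1, d2 = s2))
    tab2 <- therapy_grid_eval(model, clusters, combos2, grid)
    j <- best_viable_row(tab2)
    if (!is.na(j) && tab2$area[j] <= tab$area[i]) best <- as.numeric(combos2[j, ])
  }
  deltas <- setNames(best, clusters)
  outcome <- evaluate_therapy(model, therapy_spec(deltas), grid)
  list(deltas = deltas, outcome = outcome, viable_found = TRUE,
       coarse_table = tab)
}

#' Sensitivity analysis around an optimal therapy
#'
#' Probes the modulation factor(s) across a +/-50 percent neighborhood of the
#' optimum (clipped into `[0, 3]`; a product grid for coupled therapies) and
#' reports the gain at each probed point plus a robustness summary: the
#' fraction of viable probes retaining at least half of the peak gain. A
#' sharply peaked response (low robustness) flags an optimum that would be
#' fragile to dosing error.
#'
#' @param model A calibrated [hybrid_parameters()] bundle.
#' @param center_spec The optimal [therapy_spec()] to probe around.
#' @param grid A [time_grid()].
#' @param n_points Probes per treated cluster (default 11, symmetric around
#'   the center before clipping).
#' @return An object of class `sensitivity_report`: `center`, `table`
#'   (probed deltas, areas, viability, gain), `robustness`, `peak_gain`.
#' @export
sensitivity <- function(model, center_spec, grid, n_points = 11) {
  stopifnot(inherits(center_spec, "therapy_spec"),
            length(center_spec$deltas) >= 1)
  clusters <- names(center_spec$deltas)
  axes <- lapply(center_spec$deltas, function(d) {
    g <- seq(0.5 * d, 1.5 * d, length.out = n_points)
    sort(unique(pmin(3, pmax(0, c(g, d)))))
  })
  combos <- as.matrix(do.call(expand.grid, axes))
  colnames(combos) <- clusters
  tab <- therapy_grid_eval(model, clusters, combos, grid)
  pre <- simulate_hybrid(model, NULL, grid)
  n <- length(pre$morphology$times)
  A_pre <- pre$morphology$intimal_area[n]
  tab$gain <- ifelse(tab$viable & !tab$diverged,
                     gain_percent(A_pre, tab$area), NA_real_)
  ok <- !is.na(tab$gain)
  peak <- if (any(ok)) max(tab$gain[ok]) else NA_real_
  robustness <- if (any(ok)) mean(tab$gain[ok] >= peak / 2) else NA_real_
  structure(list(center = center_spec, table = tab, robustness = robustness,
                 peak_gain = peak, A_pre = A_pre),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %d probes, peak gain %.2f%%, robustness %.2f\n",
              nrow(x$table), x$peak_gain, x$robustness))
  invisible(x)
}

#' Screen all single and coupled gene therapies
#'
#' Optimizes each of the 5 single-cluster modulations and the 10 unordered
#' cluster pairs, attaches a sensitivity analysis to every viable optimum,
#' and returns the interventions ranked by gain.
#'
#' @param model A calibrated [hybrid_parameters()] bundle.
#' @param grid A [time_grid()].
#' @param singles_step Grid step for single-cluster search.
#' @param pair_coarse Coarse grid step for pair search.
#' @param pairs Whether to screen the 10 pairs as well.
#' @param sensitivity_points Probes per cluster in the sensitivity analysis
#'   (`0` skips it).
#' @return A data frame (class `therapy_screen`), one row per intervention:
#'   `type`, `clusters`, `delta1`, `delta2`, `gain_percent`, `viable`,
#'   `robustness`, sorted by decreasing gain.
#' @export
therapy_screen <- function(model, grid, singles_step = 0.01,
                           pair_coarse = 0.05, pairs = TRUE,
                           sensitivity_points = 11) {
  rows <- list()
  for (cl in cluster_labels()) {
    res <- optimize_single(model, cl, grid, step = singles_step)
    rob <- NA_real_
    if (res$viable_found && sensitivity_points > 0 && res$delta_min > 0) {
      rob <- sensitivity(model, res$outcome$spec, grid,
                         n_points = sensitivity_points)$robustness
    }
    rows[[length(rows) + 1L]] <- data.frame(
      type = "single", clusters = cl,
      delta1 = res$delta_min, delta2 = NA_real_,
      gain_percent = if (res$viable_found) res$outcome$gain_percent else NA_real_,
      viable = res$viable_found, robustness = rob)
  }
  if (pairs) {
    combs <- utils::combn(cluster_labels(), 2)
    for (k in seq_len(ncol(combs))) {
      cls <- combs[, k]
      res <- optimize_pair(model, cls, grid, coarse = pair_coarse)
      rob <- NA_real_
      if (res$viable_found && sensitivity_points > 0 && all(res$deltas > 0)) {
        rob <- sensitivity(model, res$outcome$spec, grid,
                           n_points = sensitivity_points)$robustness
      }
      rows[[length(rows) + 1L]] <- data.frame(
        type = "pair", clusters = paste(cls, collapse = "+"),
        delta1 = res$deltas[1], delta2 = res$deltas[2],
        gain_percent = if (res$viable_found) res$outcome$gain_percent else NA_real_,
        viable = res$viable_found, robustness = rob)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(ifelse(is.na(out$gain_percent), -Inf, out$gain_percent),
                   decreasing = TRUE), ]
  class(out) <- c("therapy_screen", "data.frame")
  out
}
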