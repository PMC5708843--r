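# Shared domain types and unit conventions.
#
# Conventions used throughout the package:
#   * time is measured in days (the 2 h sample is t = 1/12 d),
#   * expression is relative mRNA abundance (dimensionless),
#   * areas are mm^2, radii mm, shear stress Pa, viscosity cP,
#   * cluster labels "A".."E" map to indices 1..5 in that order.

#' Cluster labels
#'
#' The five significant gene clusters, labeled `A` to `E`, mapped to indices
#' 1 to 5 in that order everywhere in the package.
#'
#' @return Character vector of length 5.
#' @export
cluster_labels <- function() c("A", "B", "C", "D", "E")

#' Study sampling grid
#'
#' The sampling times of the study design: implantation (t = 0), 2 hours,
#' and 1, 3, 7, 14 and 28 days, all expressed in days.
#'
#' @param times Numeric vector of sampling times in days. Must be strictly
#'   increasing, non-negative, and start at 0.
#' @param dense_step Output step (days) for dense model trajectories.
#' @return An object of class `time_grid` with elements `times` and
#'   `dense_step`.
#' @examples
#' grid <- time_grid()
#' grid$times * 24 # hours
#' @export
time_grid <- function(times = c(0, 1 / 12, 1, 3, 7, 14, 28),
                      dense_step = 0.05) {
  if (!is.numeric(times) || length(times) < 2 || anyNA(times)) {
    stop("'times' must be a numeric vector without NAs", call. = FALSE)
  }
  if (times[1] != 0) stop("the first sampling time must be 0", call. = FALSE)
  if (any(times < 0)) stop("sampling times must be non-negative", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("sampling times must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(dense_step) || dense_step <= 0) {
    stop("'dense_step' must be a positive number", call. = FALSE)
  }
  structure(list(times = as.numeric(times), dense_step = dense_step),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat("<time_grid> ", length(x$times), " sampling times (days): ",
      paste(signif(x$times, 4), collapse = ", "),
      "; dense step ", x$dense_step, " d\n", sep = "")
  invisible(x)
}

dense_times <- function(grid, from = grid$times[1], to = max(grid$times)) {
  tt <- seq(from, to, by = grid$dense_step)
  sort(unique(c(tt, grid$times[grid$times >= from & grid$times <= to], to)))
}

#' Cluster expression time series
#'
#' Mean expression of the five gene clusters of one biologic network at the
#' study sampling times.
#'
#' @param network_id One of `"MIT"`, `"APOP"`, `"ECM"` (the cellular event the
#'   network is mapped to).
#' @param values 5 x T numeric matrix of relative expression, one row per
#'   cluster (rows named/ordered `A`..`E`), one column per sampling time.
#' @param grid A [time_grid()] with T sampling times.
#' @return An object of class `cluster_series`.
#' @export
cluster_series <- function(network_id, values, grid) {
  network_id <- match.arg(network_id, c("MIT", "APOP", "ECM"))
  values <- as.matrix(values)
  if (nrow(values) != 5) stop("'values' must have exactly 5 rows", call. = FALSE)
  if (ncol(values) != length(grid$times)) {
    stop("'values' must have one column per sampling time", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("expression values must be finite", call. = FALSE)
  if (is.null(rownames(values))) {
    rownames(values) <- cluster_labels()
  } else {
    if (anyDuplicated(rownames(values))) {
      stop("duplicate cluster labels", call. = FALSE)
    }
    if (!setequal(rownames(values), cluster_labels())) {
      stop("cluster rows must be labeled A..E", call. = FALSE)
    }
    values <- values[cluster_labels(), , drop = FALSE]
  }
  colnames(values) <- NULL
  structure(list(network_id = network_id, values = values, grid = grid),
            class = "cluster_series")
}

#' @export
print.cluster_series <- function(x, ...) {
  cat("<cluster_series> network", x$network_id, "- 5 clusters x",
      ncol(x$values), "times\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Cellular event rate time series
#'
#' Mitosis, apoptosis and ECM deposition rates at the study sampling times.
#' These are the calibration references for the cluster weights.
#'
#' @param mitosis,apoptosis,ecm Numeric vectors, one value per sampling time.
#' @param grid A [time_grid()].
#' @return An object of class `cell_event_series`.
#' @export
cell_event_series <- function(mitosis, apoptosis, ecm, grid) {
  n <- length(grid$times)
  for (v in list(mitosis, apoptosis, ecm)) {
    if (length(v) != n || !all(is.finite(v))) {
      stop("event series must be finite and match the grid length", call. = FALSE)
    }
  }
  structure(list(mitosis = as.numeric(mitosis),
                 apoptosis = as.numeric(apoptosis),
                 ecm = as.numeric(ecm), grid = grid),
            class = "cell_event_series")
}

#' Cluster network parameters
#'
#' The 33 unknowns of one cluster network: the 5 x 5 interconnection matrix
#' `A` (entry `A[j, k]` is the impact of cluster j on cluster k), the
#' asymptote vector `B` (relative expression units) and the three cubic
#' modulation coefficients `C` (units day^-3, day^-2, day^-1).
#'
#' @param A 5 x 5 numeric matrix.
#' @param B Numeric vector of length 5.
#' @param C Numeric vector of length 3.
#' @return An object of class `cn_parameters`.
#' @export
cn_parameters <- function(A, B, C = c(0, 0, 0)) {
  A <- as.matrix(A)
  if (!all(dim(A) == c(5, 5)) || !all(is.finite(A))) {
    stop("'A' must be a finite 5 x 5 matrix", call. = FALSE)
  }
  if (length(B) != 5 || !all(is.finite(B))) {
    stop("'B' must be a finite vector of length 5", call. = FALSE)
  }
  if (length(C) != 3 || !all(is.finite(C))) {
    stop("'C' must be a finite vector of length 3", call. = FALSE)
  }
  dimnames(A) <- list(cluster_labels(), cluster_labels())
  structure(list(A = A, B = setNames(as.numeric(B), cluster_labels()),
                 C = as.numeric(C)),
            class = "cn_parameters")
}

#' @export
print.cn_parameters <- function(x, ...) {
  cat("<cn_parameters> interconnection matrix A (impact of row-cluster on column-cluster):\n")
  print(round(x$A, 4))
  cat("B (asymptotes):", paste(signif(x$B, 4), collapse = ", "), "\n")
  cat("C (modulation):", paste(signif(x$C, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Validate and normalize a cluster weight vector
#'
#' Cluster weights are signed relative impacts of each cluster on a cellular
#' event, constrained to `w_i` in `[-1, 1]` with `sum(|w_i|) = 1`. Entries are
#' first clipped into `[-1, 1]` and then rescaled so the absolute values sum
#' to one.
#'
#' @param w Numeric vector of length 5, not all zero.
#' @return Numeric vector of length 5 (named `A`..`E`) satisfying both
#'   constraints.
#' @examples
#' validate_weights(c(0.5, 0.5, 0.5, -0.5, 0))
#' @export
validate_weights <- function(w) {
  if (length(w) != 5 || !is.numeric(w) || !all(is.finite(w))) {
    stop("'w' must be a finite numeric vector of length 5", call. = FALSE)
  }
  w <- pmin(1, pmax(-1, as.numeric(w)))
  s <- sum(abs(w))
  if (s == 0) stop("all-zero weight vector cannot be normalized", call. = FALSE)
  setNames(w / s, cluster_labels())
}

#' Cluster weight vector for one network
#'
#' @param network_id One of `"MIT"`, `"APOP"`, `"ECM"`.
#' @param w Numeric vector of length 5; validated with [validate_weights()].
#' @return An object of class `weight_vector` with elements `network_id`, `w`.
#' @export
weight_vector <- function(network_id, w) {
  network_id <- match.arg(network_id, c("MIT", "APOP", "ECM"))
  structure(list(network_id = network_id, w = validate_weights(w)),
            class = "weight_vector")
}

#' Unit scaling factors of the coupled model
#'
#' The 15 coefficients converting cluster expression into area-growth-rate
#' units: `beta_mit` and `beta_apop` enter the proliferation coefficient
#' alpha1(t), `beta_ecm` enters the matrix coefficient alpha2(t).
#'
#' @param beta_mit,beta_apop,beta_ecm Numeric vectors of length 5.
#' @return An object of class `scaling_factors`.
#' @export
scaling_factors <- function(beta_mit, beta_apop, beta_ecm) {
  for (v in list(beta_mit, beta_apop, beta_ecm)) {
    if (length(v) != 5 || !all(is.finite(v))) {
      stop("each beta vector must be finite and of length 5", call. = FALSE)
    }
  }
  structure(list(beta_mit = setNames(as.numeric(beta_mit), cluster_labels()),
                 beta_apop = setNames(as.numeric(beta_apop), cluster_labels()),
                 beta_ecm = setNames(as.numeric(beta_ecm), cluster_labels())),
            class = "scaling_factors")
}

#' Vessel geometry, flow and baseline mechanics
#'
#' Describes the idealized graft: a straight circumferentially symmetric
#' cylinder with lumen radius `R1`, carrying Poiseuille flow with centerline
#' velocity `U`. The baseline shear `tau0` is the arterial set point computed
#' at full flow and baseline radius; a ligated (low-flow) graft is expressed
#' by `flow_factor < 1`.
#'
#' @param A_SMC Initial cross-sectional area of the cellular (SMC) intimal
#'   component, mm^2.
#' @param A_ECM Initial cross-sectional area of the matrix component, mm^2.
#' @param R1_baseline Baseline lumen radius, mm.
#' @param U Centerline blood velocity, m/s.
#' @param mu Blood dynamic viscosity, cP (1 cP = 1e-3 Pa s).
#' @param flow_factor Dimensionless flow scaling: 1 for the high-flow graft,
#'   0.1 for the ligated side (90 percent flow reduction).
#' @param tau0 Baseline (arterial) shear stress, Pa. Defaults to the shear at
#'   full flow and baseline radius, `2 * mu * U / R1_baseline` = 6.4 Pa for
#'   the default geometry.
#' @return An object of class `vessel_state`.
#' @examples
#' vessel_state()$tau0 # 6.4 Pa
#' @export
vessel_state <- function(A_SMC = 0.04, A_ECM = 0.02, R1_baseline = 1,
                         U = 1, mu = 3.2, flow_factor = 0.1, tau0 = NULL) {
  if (A_SMC < 0 || A_ECM < 0) stop("areas must be non-negative", call. = FALSE)
  if (R1_baseline <= 0) stop("'R1_baseline' must be positive", call. = FALSE)
  if (mu <= 0) stop("'mu' must be positive", call. = FALSE)
  if (flow_factor < 0) stop("'flow_factor' must be non-negative", call. = FALSE)
  # mu [cP] * 1e-3 [Pa s/cP] * 2U [m/s] / (R1 [mm] * 1e-3 [m/mm]): the 1e-3
  # factors cancel, so tau [Pa] = 2 * mu_cP * U_mps / R1_mm.
  if (is.null(tau0)) tau0 <- 2 * mu * U / R1_baseline
  structure(list(A_SMC = A_SMC, A_ECM = A_ECM,
                 R1 = R1_baseline, R1_baseline = R1_baseline,
                 U = U, mu = mu, flow_factor = flow_factor, tau0 = tau0),
            class = "vessel_state")
}

#' @export
print.vessel_state <- function(x, ...) {
  cat(sprintf(paste0("<vessel_state> R1 = %g mm (baseline %g), U = %g m/s, ",
                     "mu = %g cP, flow_factor = %g, tau0 = %g Pa\n",
                     "  A_SMC = %g mm^2, A_ECM = %g mm^2\n"),
              x$R1, x$R1_baseline, x$U, x$mu, x$flow_factor, x$tau0,
              x$A_SMC, x$A_ECM))
  invisible(x)
}

#' Gene therapy specification
#'
#' A therapy is a constant modulation of one or two clusters: each treated
#' cluster starts at `delta` times its untreated initial expression and is
#' held at that value for the whole 28-day follow-up (`delta < 1` inhibition,
#' `delta = 1` freeze at baseline, `delta > 1` overexpression, capped 3-fold).
#'
#' @param deltas Named numeric vector or list, names among `A`..`E`, values in
#'   `[0, 3]`, at most two entries. An empty vector is the untreated case.
#' @return An object of class `therapy_spec`.
#' @examples
#' therapy_spec(c(C = 0.6))
#' therapy_spec(c(C = 0.97, D = 2.64))
#' @export
therapy_spec <- function(deltas = numeric(0)) {
  deltas <- unlist(deltas)
  if (length(deltas) > 0) {
    if (is.null(names(deltas)) || !all(names(deltas) %in% cluster_labels())) {
      stop("'deltas' must be named with cluster labels A..E", call. = FALSE)
    }
    if (anyDuplicated(names(deltas))) stop("duplicate cluster in therapy", call. = FALSE)
    if (length(deltas) > 2) {
      stop("at most two clusters can be modulated (single or coupled therapy)",
           call. = FALSE)
    }
    if (any(!is.finite(deltas)) || any(deltas < 0) || any(deltas > 3)) {
      stop("each delta must lie in [0, 3]", call. = FALSE)
    }
  }
  structure(list(deltas = deltas), class = "therapy_spec")
}

#' @export
print.therapy_spec <- function(x, ...) {
  if (length(x$deltas) == 0) {
    cat("<therapy_spec> untreated\n")
  } else {
    cat("<therapy_spec>",
        paste(sprintf("%s: delta = %g", names(x$deltas), x$deltas),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Genetic algorithm configuration
#'
#' @param pop_multiplier Population size as a multiple of the number of
#'   unknowns (study default 100).
#' @param generations Generations per run.
#' @param n_restarts Number of recursive restart runs after the first, each
#'   re-seeded inside a shrunken neighborhood of the previous best.
#' @param restart_shrink Fraction of the previous search width retained around
#'   the incumbent best at each restart (recursive refinement).
#' @param tolerance Knockdown-stability tolerance `Tol` on the sum-of-squares
#'   misfit of the four free clusters (study value 10).
#' @param seed Integer seed; a fixed seed makes the run reproducible.
#' @param crossover_prob,mutation_prob Per-pair / per-gene operator rates
#'   (`mutation_prob = NULL` uses 1.5 / n_unknowns).
#' @param elite_n Number of elite individuals copied unchanged.
#' @param sigma_start,sigma_end Gaussian mutation s.d. as a fraction of the
#'   bound width, decayed linearly across generations.
#' @param stop_value Early-stop threshold: a run ends once the best objective
#'   is at or below this value (default `NULL`, no early stop).
#' @param stall_gens End a run early when the best objective has not improved
#'   (relatively, by 1e-3) for this many generations (default `NULL`, off).
#' @param pop_size Optional explicit population size overriding
#'   `pop_multiplier * n_unknowns`.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_multiplier = 100, generations = 100, n_restarts = 2,
                      restart_shrink = 0.1, tolerance = 10, seed = NULL,
                      crossover_prob = 0.9, mutation_prob = NULL, elite_n = 2,
                      sigma_start = 0.15, sigma_end = 0.02,
                      stop_value = NULL, stall_gens = NULL, pop_size = NULL) {
  if (pop_multiplier < 1) stop("'pop_multiplier' must be >= 1", call. = FALSE)
  if (tolerance <= 0) stop("'tolerance' must be positive", call. = FALSE)
  if (n_restarts < 0) stop("'n_restarts' must be >= 0", call. = FALSE)
  structure(list(pop_multiplier = pop_multiplier, generations = generations,
                 n_restarts = n_restarts, restart_shrink = restart_shrink,
                 tolerance = tolerance, seed = seed,
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 elite_n = elite_n, sigma_start = sigma_start,
                 sigma_end = sigma_end, stop_value = stop_value,
                 stall_gens = stall_gens, pop_size = pop_size),
            class = "ga_config")
}

# ---------------------------------------------------------------------------
# Delimited table I/O

fmt_num <- function(x) sprintf("%.17g", x)

detect_sep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (grepl("\t", l1)) "\t" else ","
}

#' Read a time-course table
#'
#' Reads a delimited (CSV or TSV) time-course table with a `time` column in
#' days. Three schemas mirror the study's supplementary data layouts:
#' `"clusters"` (columns `time, A..E`, one biologic network), `"events"`
#' (columns `time, mitosis, apoptosis, ecm`), and `"thickness"` (columns
#' `time, thickness`). Unknown extra columns are reported with a message and
#' ignored.
#'
#' @param path File path.
#' @param schema_id One of `"clusters"`, `"events"`, `"thickness"`.
#' @param network_id Network tag required for `schema_id = "clusters"`.
#' @param grid Optional [time_grid()]; if supplied, the file must contain
#'   exactly these times (missing ones are an error listing the absent times).
#' @param dense_step Dense step of the grid built from the file times when
#'   `grid` is not given.
#' @return A [cluster_series()], [cell_event_series()], or a list with
#'   elements `thickness` and `grid`.
#' @export
read_timecourse_table <- function(path, schema_id = c("clusters", "events", "thickness"),
                                  network_id = NULL, grid = NULL,
                                  dense_step = 0.05) {
  schema_id <- match.arg(schema_id)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"time" %in% names(df)) stop("no 'time' column in ", path, call. = FALSE)
  for (cn in names(df)) {
    if (!is.numeric(df[[cn]])) {
      stop("non-numeric values in column '", cn, "' of ", path, call. = FALSE)
    }
  }
  df <- df[order(df$time), , drop = FALSE]
  if (!is.null(grid)) {
    missing_t <- setdiff(signif(grid$times, 10), signif(df$time, 10))
    if (length(missing_t) > 0) {
      stop("missing sampling times (days) in ", path, ": ",
           paste(signif(missing_t, 6), collapse = ", "), call. = FALSE)
    }
    df <- df[match(signif(grid$times, 10), signif(df$time, 10)), , drop = FALSE]
  } else {
    grid <- time_grid(df$time, dense_step = dense_step)
  }
  expected <- switch(schema_id,
    clusters = cluster_labels(),
    events = c("mitosis", "apoptosis", "ecm"),
    thickness = "thickness")
  unknown <- setdiff(names(df), c("time", expected))
  if (length(unknown) > 0) {
    message("ignoring unknown column(s) in ", basename(path), ": ",
            paste(unknown, collapse = ", "))
  }
  absent <- setdiff(expected, names(df))
  if (length(absent) > 0) {
    stop("missing column(s) in ", path, ": ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  switch(schema_id,
    clusters = {
      if (is.null(network_id)) stop("'network_id' required for cluster tables",
                                    call. = FALSE)
      cluster_series(network_id, t(as.matrix(df[, cluster_labels()])), grid)
    },
    events = cell_event_series(df$mitosis, df$apoptosis, df$ecm, grid),
    thickness = list(thickness = df$thickness, grid = grid))
}

#' Write a time-course table
#'
#' Inverse of [read_timecourse_table()]; values are written with 17
#' significant digits so a write/read round trip is bit-identical.
#'
#' @param x A `cluster_series`, `cell_event_series`, or a list with
#'   `thickness` and `grid`.
#' @param path Output file; extension `.tsv` selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_timecourse_table <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- if (inherits(x, "cluster_series")) {
    cbind(data.frame(time = x$grid$times),
          as.data.frame(t(x$values), col.names = cluster_labels()))
  } else if (inherits(x, "cell_event_series")) {
    data.frame(time = x$grid$times, mitosis = x$mitosis,
               apoptosis = x$apoptosis, ecm = x$ecm)
  } else if (is.list(x) && !is.null(x$thickness)) {
    data.frame(time = x$grid$times, thickness = x$thickness)
  } else {
    stop("unsupported object for time-course writing", call. = FALSE)
  }
  out <- as.data.frame(lapply(df, fmt_num), check.names = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# JSON parameter bundles

as_param_list <- function(x) {
  if (inherits(x, "cn_parameters")) {
    list(type = "cn_parameters", A = unname(x$A), B = unname(x$B), C = x$C)
  } else if (inherits(x, "weight_vector")) {
    list(type = "weight_vector", network_id = x$network_id, w = unname(x$w))
  } else if (inherits(x, "scaling_factors")) {
    list(type = "scaling_factors", beta_mit = unname(x$beta_mit),
         beta_apop = unname(x$beta_apop), beta_ecm = unname(x$beta_ecm))
  } else if (inherits(x, "therapy_spec")) {
    list(type = "therapy_spec",
         clusters = names(x$deltas), deltas = unname(x$deltas))
  } else if (inherits(x, "vessel_state")) {
    c(list(type = "vessel_state"), unclass(x))
  } else if (inherits(x, "hybrid_parameters")) {
    list(type = "hybrid_parameters", schema_version = 1L,
         cn_mit = as_param_list(x$cn_mit), cn_apop = as_param_list(x$cn_apop),
         cn_ecm = as_param_list(x$cn_ecm),
         weights = lapply(x$weights, as_param_list),
         scaling = as_param_list(x$scaling),
         scenario = as_param_list(x$scenario),
         g0 = x$g0)
  } else {
    stop("no JSON representation for class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
}

from_param_list <- function(l) {
  switch(l$type,
    cn_parameters = cn_parameters(matrix(unlist(l$A), 5, 5), unlist(l$B),
                                  unlist(l$C)),
    weight_vector = weight_vector(l$network_id, unlist(l$w)),
    scaling_factors = scaling_factors(unlist(l$beta_mit), unlist(l$beta_apop),
                                      unlist(l$beta_ecm)),
    therapy_spec = therapy_spec(setNames(unlist(l$deltas),
                                         unlist(l$clusters))),
    vessel_state = vessel_state(A_SMC = l$A_SMC, A_ECM = l$A_ECM,
                                R1_baseline = l$R1_baseline, U = l$U,
                                mu = l$mu, flow_factor = l$flow_factor,
                                tau0 = l$tau0),
    hybrid_parameters = hybrid_parameters(
      cn_mit = from_param_list(l$cn_mit),
      cn_apop = from_param_list(l$cn_apop),
      cn_ecm = from_param_list(l$cn_ecm),
      weights = lapply(l$weights, from_param_list),
      scaling = from_param_list(l$scaling),
      scenario = from_param_list(l$scenario),
      g0 = lapply(l$g0, unlist)),
    stop("unknown parameter bundle type: ", l$type, call. = FALSE))
}

#' Save or load parameter objects as JSON
#'
#' Serializes the package's parameter objects (`cn_parameters`,
#' `weight_vector`, `scaling_factors`, `therapy_spec`, `vessel_state`,
#' `hybrid_parameters`) to a self-describing JSON file.
#'
#' @param x Parameter object.
#' @param path JSON file path.
#' @return `save_parameters()` returns `path` invisibly; `load_parameters()`
#'   returns the reconstructed object.
#' @export
save_parameters <- function(x, path) {
  jsonlite::write_json(as_param_list(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_parameters
#' @export
load_parameters <- function(path) {
  from_param_list(jsonlite::read_json(path, simplifyVector = TRUE))
}
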