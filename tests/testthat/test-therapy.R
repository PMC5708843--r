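test_that("an untreated therapy has zero gain", {
  grid <- time_grid()
  out <- evaluate_therapy(demo_model(), therapy_spec(), grid)
  expect_true(out$viable)
  expect_equal(out$gain_percent, 0)
  expect_equal(out$A_pre, out$A_post)
})

test_that("gain is the normalized area reduction and is unit-invariant", {
  expect_equal(graftnet:::gain_percent(2, 1), 50)
  expect_equal(graftnet:::gain_percent(2, 0.04), 98)
  expect_equal(graftnet:::gain_percent(10 * 2, 10 * 1), 50) # rescaled units
  expect_equal(graftnet:::gain_percent(1, 1.5), -50) # worsening is negative
})

test_that("overexpressing a strong inhibitory cluster is rejected as non-viable", {
  # decoupled network, constant expression; cluster B carries weight -0.5 on
  # mitosis, so tripling it drives phi_mit = 0.5*1 - 0.5*3 < 0
  cnp <- cn_parameters(matrix(0, 5, 5), rep(0, 5), c(0, 0, 0))
  w <- c(0.5, -0.5, 0, 0, 0)
  weights <- list(weight_vector("MIT", w), weight_vector("APOP", c(1, 0, 0, 0, 0)),
                  weight_vector("ECM", c(1, 0, 0, 0, 0)))
  beta <- c(0.05, 0.05, 0, 0, 0)
  hp <- hybrid_parameters(cnp, cnp, cnp, weights,
                          scaling_factors(beta, 0.2 * beta, 0.5 * beta),
                          vessel_state(), list(MIT = rep(1, 5),
                                               APOP = rep(1, 5),
                                               ECM = rep(1, 5)))
  out <- evaluate_therapy(hp, therapy_spec(c(B = 3)), grid = time_grid())
  expect_false(out$viable)
  expect_true(is.na(out$gain_percent))
  # direct inspection: the weighted mitosis combination is negative
  expect_lt(min(out$trajectories$post$phi$mit), 0)
  # the same cluster frozen at baseline keeps phi at zero and stays viable
  out1 <- evaluate_therapy(hp, therapy_spec(c(B = 1)), grid = time_grid())
  expect_true(out1$viable)
})

test_that("an inert cluster produces a flat therapy response", {
  grid <- time_grid()
  hp <- inert_E_model()
  res <- optimize_single(hp, "E", grid, step = 0.25)
  expect_true(res$viable_found)
  expect_lt(diff(range(res$table$area)), 1e-9)
  expect_equal(res$delta_min, 0) # tie rule: smallest delta wins
  expect_lt(abs(res$outcome$gain_percent), 1e-6)
})

test_that("pairing with an inert cluster recovers the single-cluster optimum", {
  grid <- time_grid()
  hp <- inert_E_model()
  single <- optimize_single(hp, "A", grid, step = 0.05)
  pair <- optimize_pair(hp, c("A", "E"), grid, coarse = 0.05, refine = FALSE)
  expect_equal(unname(pair$deltas["A"]), single$delta_min, tolerance = 1e-9)
  expect_equal(pair$outcome$gain_percent, single$outcome$gain_percent,
               tolerance = 1e-6)
})

test_that("grid search matches direct exhaustive enumeration", {
  grid <- time_grid()
  hp <- demo_model()
  dd <- seq(0, 3, by = 0.25)
  res <- optimize_single(hp, "B", grid, step = 0.25)
  # oracle: evaluate every delta independently through the full model run
  areas <- vapply(dd, function(d) {
    out <- evaluate_therapy(hp, therapy_spec(c(B = d)), grid)
    if (out$viable) out$A_post else NA_real_
  }, numeric(1))
  expect_equal(res$delta_min, dd[which.min(areas)])
  expect_lt(max(abs(res$table$area - areas), na.rm = TRUE), 1e-4)
})

test_that("a tenfold finer grid moves the optimum by at most one coarse step", {
  grid <- time_grid()
  hp <- demo_model()
  for (cl in c("B", "E")) {
    coarse <- optimize_single(hp, cl, grid, step = 0.1)
    fine <- optimize_single(hp, cl, grid, step = 0.01)
    expect_lte(abs(coarse$delta_min - fine$delta_min), 0.1 + 1e-9)
  }
})

test_that("sensitivity probes are symmetric around the center and contain it", {
  grid <- time_grid()
  hp <- inert_E_model()
  rep1 <- sensitivity(hp, therapy_spec(c(A = 1)), grid, n_points = 11)
  dd <- rep1$table[, 1]
  expect_true(any(abs(dd - 1) < 1e-12))
  expect_equal(range(dd), c(0.5, 1.5))
  expect_equal(sort(dd), sort(2 - dd), tolerance = 1e-9) # symmetric pre-clip
  # flat-response model: every probed gain equal
  repE <- sensitivity(hp, therapy_spec(c(E = 1)), grid, n_points = 7)
  expect_lt(diff(range(repE$table$gain)), 1e-9)
  expect_equal(repE$robustness, 1)
})

test_that("probes beyond the overexpression cap are clipped", {
  grid <- time_grid()
  hp <- inert_E_model()
  rep3 <- sensitivity(hp, therapy_spec(c(A = 2.5)), grid, n_points = 11)
  dd <- rep3$table[, 1]
  expect_true(all(dd <= 3 & dd >= 1.25))
  expect_true(any(abs(dd - 2.5) < 1e-12))
})

test_that("the demonstration model shows heterogeneous therapy directions", {
  # some clusters help when silenced, others when maximally overexpressed
  grid <- time_grid()
  hp <- demo_model()
  ends <- vapply(cluster_labels(), function(cl) {
    tab <- graftnet:::therapy_grid_eval(hp, cl, matrix(c(0, 3), ncol = 1), grid)
    tab$area
  }, numeric(2))
  expect_true(any(ends[1, ] < ends[2, ])) # inhibition-optimal cluster exists
  expect_true(any(ends[1, ] > ends[2, ])) # overexpression-optimal too
})
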