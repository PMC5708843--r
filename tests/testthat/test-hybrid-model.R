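make_cn_results <- function(model, grid) {
  list(MIT = simulate_network(model$cn_mit, model$g0$MIT, grid),
       APOP = simulate_network(model$cn_apop, model$g0$APOP, grid),
       ECM = simulate_network(model$cn_ecm, model$g0$ECM, grid))
}

test_that("alpha coefficients reduce correctly in degenerate configurations", {
  grid <- time_grid()
  hp <- inert_E_model()
  cn <- make_cn_results(hp, grid)
  tt <- c(0, 1, 7, 28)

  hp0 <- hp
  hp0$scaling <- scaling_factors(rep(0, 5), rep(0, 5), rep(0, 5))
  expect_equal(alpha1(tt, hp0, cn), rep(0, 4))
  expect_equal(alpha2(tt, hp0, cn), rep(0, 4))

  # single-term reduction: alpha1(t) = G_A^Mit(t)
  hp1 <- hp
  hp1$weights <- list(MIT = weight_vector("MIT", c(1, 0, 0, 0, 0)),
                      APOP = hp$weights$APOP, ECM = hp$weights$ECM)
  hp1$scaling <- scaling_factors(c(5, 0, 0, 0, 0), rep(0, 5), rep(0, 5))
  cn1 <- make_cn_results(hp1, grid)
  gA <- graftnet:::cn_at(cn1$MIT, tt)[1, ]
  expect_equal(alpha1(tt, hp1, cn1), gA, tolerance = 1e-9)

  # balanced mitosis and apoptosis cancel exactly (identical networks here)
  hp2 <- hp1
  hp2$weights$APOP <- weight_vector("APOP", c(1, 0, 0, 0, 0))
  hp2$scaling <- scaling_factors(c(5, 0, 0, 0, 0), c(5, 0, 0, 0, 0), rep(0, 5))
  cn2 <- make_cn_results(hp2, grid)
  expect_equal(alpha1(tt, hp2, cn2), rep(0, 4), tolerance = 1e-12)

  # uniform ECM weights with beta = 5 give the plain cluster mean
  hp3 <- hp
  hp3$weights$ECM <- weight_vector("ECM", rep(0.2, 5))
  hp3$scaling <- scaling_factors(rep(0, 5), rep(0, 5), rep(5, 5))
  cn3 <- make_cn_results(hp3, grid)
  expect_equal(alpha2(tt, hp3, cn3),
               colMeans(graftnet:::cn_at(cn3$ECM, tt)), tolerance = 1e-9)

  # sign flip of the ECM weights flips alpha2
  hp4 <- hp3
  hp4$weights$ECM <- weight_vector("ECM", rep(-0.2, 5))
  expect_equal(alpha2(tt, hp4, cn3), -alpha2(tt, hp3, cn3))

  expect_error(alpha1(29, hp, cn), "outside")
})

test_that("alpha coefficients are linear in the scaling factors", {
  grid <- time_grid()
  hp <- demo_model()
  cn <- make_cn_results(hp, grid)
  tt <- c(0.5, 3, 14, 28)
  hp2 <- hp
  hp2$scaling <- scaling_factors(3 * hp$scaling$beta_mit,
                                 3 * hp$scaling$beta_apop,
                                 3 * hp$scaling$beta_ecm)
  expect_equal(alpha1(tt, hp2, cn), 3 * alpha1(tt, hp, cn), tolerance = 1e-12)
  expect_equal(alpha2(tt, hp2, cn), 3 * alpha2(tt, hp, cn), tolerance = 1e-12)
})

test_that("PRMS behaves as a normalized percentage deviation", {
  x <- c(0.01, 0.05, 0.1, 0.2, 0.35, 0.4)
  expect_equal(prms(x, x), 0)
  expect_equal(prms(x, 1.01 * x), 1, tolerance = 1e-9)
  expect_equal(prms(x, 0 * x), 100)
  expect_error(prms(rep(0, 6), x), "zero norm")
  expect_error(prms(x, x[-1]), "aligned")
})

test_that("an absent therapy and an empty therapy are identical", {
  grid <- time_grid()
  hp <- demo_model()
  s1 <- simulate_hybrid(hp, NULL, grid)
  s2 <- simulate_hybrid(hp, therapy_spec(), grid)
  expect_identical(s1$morphology$intimal_area, s2$morphology$intimal_area)
  expect_identical(s1$phi$mit, s2$phi$mit)
})

test_that("a zero-coupling model reduces to the constant-coefficient system", {
  grid <- time_grid()
  hp <- inert_E_model()
  # remove the self-decay: expression is pinned at its initial value, so the
  # coupled model must collapse onto the plain constant-alpha wall model
  cn0 <- cn_parameters(matrix(0, 5, 5), rep(1, 5), c(0, 0, 0))
  hp$cn_mit <- hp$cn_apop <- hp$cn_ecm <- cn0
  sim <- simulate_hybrid(hp, NULL, grid)
  expect_lt(diff(range(sim$alpha$alpha1)), 1e-10) # alpha constant in time
  ds <- simulate_ds(sim$alpha$alpha1[1], sim$alpha$alpha2[1], hp$scenario, grid)
  expect_lt(max(abs(ds$intimal_area - sim$morphology$intimal_area)), 1e-7)
  # the same holds when the inert cluster is additionally frozen by a therapy
  sim2 <- simulate_hybrid(hp, therapy_spec(c(E = 1)), grid)
  expect_equal(sim2$morphology$intimal_area, sim$morphology$intimal_area,
               tolerance = 1e-12)
})

test_that("full flow suppresses wall growth regardless of gene dynamics", {
  grid <- time_grid()
  hp <- demo_model()
  hp$scenario <- vessel_state(flow_factor = 1)
  sim <- simulate_hybrid(hp, NULL, grid)
  expect_lt(diff(range(sim$morphology$intimal_area)), 1e-10)
})

test_that("the coupled model departs from the constant-coefficient exponential", {
  grid <- time_grid()
  hp <- demo_model()
  sim <- simulate_hybrid(hp, NULL, grid)
  a1_mean <- mean(sim$alpha$alpha1)
  a2_mean <- mean(sim$alpha$alpha2)
  ds <- simulate_ds(a1_mean, a2_mean, hp$scenario, grid)
  late <- sim$morphology$times > 1
  ratio <- sim$morphology$intimal_thickness[late] / ds$intimal_thickness[late]
  # non-proportional trajectories: the ratio is far from constant
  expect_gt(diff(range(ratio)) / mean(ratio), 0.05)
})

test_that("the truth model reproduces the generated noise-free thickness", {
  ds <- demo_dataset0()
  hp <- demo_model()
  sim <- simulate_hybrid(hp, NULL, ds$grid, ds_method = "rk4")
  th <- sim$morphology$intimal_thickness[match(ds$grid$times,
                                               sim$morphology$times)]
  post <- ds$grid$times > 0
  expect_lt(prms(ds$thickness[post], th[post]), 0.1)
})
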