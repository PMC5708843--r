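# Stage-level calibration behavior on small budgets.  The deeper
# recovery checks (full chain, study-scale budgets) live in the
# acceptance suite.

test_that("an equilibrium reference is fitted to near-zero misfit", {
  grid <- time_grid()
  B <- c(1.2, 0.9, 1.5, 0.7, 1.1)
  ref <- cluster_series("MIT", matrix(B, 5, 7), grid)
  res <- calibrate_cn(ref, ga_config(pop_multiplier = 20, generations = 60,
                                     n_restarts = 3, stall_gens = 15,
                                     seed = 2),
                      n_runs = 1)
  # G0 = B makes any interconnection matrix an exact fit (A = 0 family)
  expect_lt(res$objective, 1e-2)
  expect_true(all(res$stability_report$stable))
  expect_s3_class(res$params, "cn_parameters")
})

test_that("calibrated parameters always pass the knockdown screen", {
  ds <- demo_dataset0()
  res <- calibrate_cn(ds$clusters$APOP,
                      ga_config(pop_multiplier = 30, generations = 60,
                                n_restarts = 2, stall_gens = 15, seed = 4),
                      n_runs = 1)
  expect_true(all(res$stability_report$stable))
  expect_true(all(res$stability_report$rms <= 10))
  tr <- res$restart_trace[is.finite(res$restart_trace)]
  expect_true(all(diff(tr) <= 0))
})

test_that("weights are recovered from a known sparse combination", {
  # events constructed as 0.4 G_A - 0.6 G_B on distinguishable curves
  sims <- demo_truth_sims()
  grid <- demo_truth()$grid
  w_true <- c(0.4, -0.6, 0, 0, 0)
  mk_event <- function(net) {
    as.numeric(crossprod(graftnet:::cn_at(sims[[net]], grid$times), w_true))
  }
  events <- cell_event_series(mk_event("MIT"), mk_event("APOP"),
                              mk_event("ECM"), grid)
  res <- calibrate_weights(sims, events,
                           ga_config(generations = 120, n_restarts = 10,
                                     restart_shrink = 0.6, sigma_end = 0.002,
                                     stall_gens = 25, stop_value = 1e-6,
                                     seed = 6),
                           n_runs = 3)
  for (net in c("MIT", "APOP", "ECM")) {
    expect_lt(max(abs(res$params[[net]]$w - w_true)), 0.05)
  }
})

test_that("an event equal to one cluster's expression recovers a unit weight", {
  sims <- demo_truth_sims()
  grid <- demo_truth()$grid
  gC <- graftnet:::cn_at(sims$MIT, grid$times)[3, ]
  events <- cell_event_series(gC,
                              graftnet:::cn_at(sims$APOP, grid$times)[3, ],
                              graftnet:::cn_at(sims$ECM, grid$times)[3, ],
                              grid)
  res <- calibrate_weights(sims, events,
                           ga_config(generations = 120, n_restarts = 10,
                                     restart_shrink = 0.6, sigma_end = 0.002,
                                     stall_gens = 25, stop_value = 1e-6,
                                     seed = 8),
                           n_runs = 3)
  expect_lt(res$per_network[["MIT"]], 1e-4)
  expect_lt(max(abs(res$params$MIT$w - c(0, 0, 1, 0, 0))), 0.05)
})

test_that("returned weight vectors satisfy the constraint set exactly", {
  ds <- demo_dataset0()
  sims <- demo_truth_sims()
  res <- calibrate_weights(sims, ds$events,
                           ga_config(generations = 30, seed = 10),
                           n_runs = 1)
  for (net in c("MIT", "APOP", "ECM")) {
    w <- res$params[[net]]$w
    expect_equal(sum(abs(w)), 1, tolerance = 1e-9)
    expect_true(all(abs(w) <= 1 + 1e-12))
  }
})

test_that("degenerate all-zero trajectories are rejected", {
  grid <- time_grid()
  p0 <- cn_parameters(matrix(0, 5, 5), rep(0, 5), c(0, 0, 0))
  zero_sims <- list(
    MIT = simulate_network(p0, rep(0, 5), grid),
    APOP = simulate_network(p0, rep(0, 5), grid),
    ECM = simulate_network(p0, rep(0, 5), grid))
  events <- cell_event_series(rep(1, 7), rep(1, 7), rep(1, 7), grid)
  expect_error(calibrate_weights(zero_sims, events,
                                 ga_config(generations = 5, seed = 1),
                                 n_runs = 1),
               "degenerate")
})

test_that("zero scaling bounds leave a flat wall and 100% deviation", {
  tr <- demo_truth()
  ds <- demo_dataset0()
  res <- calibrate_scaling(tr$cn$MIT, tr$cn$APOP, tr$cn$ECM, tr$g0,
                           tr$weights, tr$scenario, ds$thickness, tr$grid,
                           ga_config(pop_size = 30, generations = 2, seed = 1),
                           bounds = c(0, 0), n_runs = 1)
  expect_equal(res$prms, 100, tolerance = 1e-6)
})

test_that("the flow-scaling degeneracy leaves the wall trajectory unchanged", {
  # doubling the centerline velocity doubles both tau and tau0; halving every
  # scaling factor then reproduces the same alpha * shear-deficit product
  grid <- time_grid()
  hp <- demo_model()
  hp2 <- hp
  hp2$scenario <- vessel_state(A_SMC = hp$scenario$A_SMC,
                               A_ECM = hp$scenario$A_ECM,
                               R1_baseline = hp$scenario$R1_baseline,
                               U = 2 * hp$scenario$U, mu = hp$scenario$mu,
                               flow_factor = hp$scenario$flow_factor)
  hp2$scaling <- scaling_factors(hp$scaling$beta_mit / 2,
                                 hp$scaling$beta_apop / 2,
                                 hp$scaling$beta_ecm / 2)
  s1 <- simulate_hybrid(hp, NULL, grid)
  s2 <- simulate_hybrid(hp2, NULL, grid)
  expect_lt(max(abs(s1$morphology$intimal_area - s2$morphology$intimal_area)),
            1e-7)
})
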