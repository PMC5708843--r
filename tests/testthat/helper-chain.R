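# Full chained calibration on the noise-free demonstration dataset, computed
# once and shared by the acceptance-style tests.  Problem sizes follow the
# desk-scale budgets documented in the methods vignette.

demo_chain <- function() {
  memo("chain", {
    ds <- demo_dataset0()
    grid <- ds$grid
    stopv <- (0.005 * sqrt(sum(ds$thickness[grid$times > 0]^2)))^2
    cn_cfg <- ga_config(pop_multiplier = 30, generations = 80, n_restarts = 2,
                        stall_gens = 15, seed = 11)
    w_cfg <- ga_config(generations = 120, n_restarts = 10,
                       restart_shrink = 0.6, sigma_end = 0.002,
                       stall_gens = 25, seed = 11)
    b_cfg <- ga_config(generations = 150, n_restarts = 10,
                       restart_shrink = 0.5, sigma_end = 0.001,
                       stall_gens = 25, stop_value = stopv, seed = 11)
    calibrate_pipeline(ds, vessel_state(), cn_cfg, w_cfg, b_cfg,
                       n_runs = c(cn = 1, weights = 1, scaling = 2))
  })
}

demo_chain_screen <- function() {
  memo("chain_screen", {
    therapy_screen(demo_chain()$hybrid, demo_truth()$grid,
                   singles_step = 0.01, pair_coarse = 0.1,
                   sensitivity_points = 0)
  })
}
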