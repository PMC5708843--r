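# Shared fixtures.  Expensive objects are memoized for the whole test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

demo_truth <- function() memo("truth", make_ground_truth(101))

demo_dataset0 <- function() {
  memo("dataset0",
       generate_dataset(demo_truth(),
                        noise = c(expression = 0, rates = 0, thickness = 0)))
}

demo_model <- function() memo("model", truth_parameters(demo_truth()))

demo_truth_sims <- function() {
  memo("truth_sims", {
    tr <- demo_truth()
    lapply(c(MIT = "MIT", APOP = "APOP", ECM = "ECM"), function(net) {
      simulate_network(tr$cn[[net]], tr$g0[[net]], tr$grid, method = "exact")
    })
  })
}

# A fully inert cluster E: zero weights and zero couplings in every network.
# Other clusters keep simple stable self-decay, so therapies on E are flat.
inert_E_model <- function(alpha_scale = 0.05) {
  A <- -0.3 * diag(5)
  A[5, ] <- 0
  A[, 5] <- 0
  B <- rep(1, 5)
  cnp <- cn_parameters(A, B, c(0, 0, 0))
  w <- validate_weights(c(0.4, 0.3, 0.2, 0.1, 0))
  weights <- list(weight_vector("MIT", w), weight_vector("APOP", w),
                  weight_vector("ECM", w))
  beta <- alpha_scale * sign(w)
  scaling <- scaling_factors(beta, 0.3 * beta, 0.5 * beta)
  g0 <- rep(1.2, 5)
  hybrid_parameters(cnp, cnp, cnp, weights, scaling, vessel_state(),
                    list(MIT = g0, APOP = g0, ECM = g0))
}
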