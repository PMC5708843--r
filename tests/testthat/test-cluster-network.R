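test_that("the cubic modulation mask evaluates its polynomial", {
  expect_equal(eval_modulation(c(2, -1, 0.5), 0), 1)
  expect_equal(eval_modulation(c(0, 0, 0), 17.3), 1)
  expect_equal(eval_modulation(c(1, 1, 1), 2), 15)
  expect_equal(eval_modulation(c(0.5, 0, -1), c(0, 1, 2)), c(1, 0.5, 3))
})

test_that("zero coupling keeps every trajectory at its initial value", {
  g <- time_grid()
  p <- cn_parameters(matrix(0, 5, 5), runif(5), c(0.1, -0.2, 0.3))
  G0 <- c(1.2, 0.8, 1.5, 0.6, 1.0)
  sim <- simulate_network(p, G0, g)
  expect_false(sim$flags$diverged)
  expect_equal(max(abs(sim$trajectories - G0)), 0, tolerance = 1e-8)
})

test_that("freezing all five clusters pins the state regardless of coupling", {
  g <- time_grid()
  set.seed(5)
  p <- cn_parameters(matrix(rnorm(25, sd = 2), 5, 5), rnorm(5), c(0, 0, 0.5))
  G0 <- runif(5, 0.5, 1.5)
  sim <- simulate_network(p, G0, g, frozen = cluster_labels())
  expect_equal(max(abs(sim$trajectories - G0)), 0, tolerance = 1e-10)
})

test_that("the asymptote vector is an equilibrium for any coupling", {
  g <- time_grid()
  set.seed(6)
  for (i in 1:5) {
    B <- runif(5, 0.5, 2)
    p <- cn_parameters(matrix(rnorm(25), 5, 5), B, rnorm(3) / 50)
    sim <- simulate_network(p, B, g)
    expect_lt(max(abs(sim$trajectories - B)), 1e-7)
  }
})

test_that("simulation matches the matrix-exponential solution of the linear case", {
  # independent oracle: Matrix::expm on the constant-coefficient system
  g <- time_grid()
  set.seed(8)
  for (i in 1:5) {
    M <- matrix(rnorm(25, sd = 0.4), 5, 5)
    diag(M) <- diag(M) - 1          # comfortably stable
    A <- t(M)
    B <- runif(5, 0.5, 1.5)
    G0 <- runif(5, 0.5, 1.5)
    p <- cn_parameters(A, B, c(0, 0, 0))  # lambda identically 1
    for (method in c("ode", "exact")) {
      sim <- simulate_network(p, G0, g, method = method)
      idx <- match(g$times, sim$times)
      for (k in seq_along(g$times)) {
        expected <- B + as.numeric(
          Matrix::expm(M * g$times[k]) %*% (G0 - B))
        got <- sim$trajectories[, idx[k]]
        expect_lt(max(abs(got - expected)) / max(1, max(abs(expected))), 1e-6)
      }
    }
  }
})

test_that("a diagonal decay network follows the scalar exponential", {
  g <- time_grid()
  p <- cn_parameters(-diag(5), rep(0, 5), c(0, 0, 0))
  G0 <- c(1, 2, 3, 4, 5)
  sim <- simulate_network(p, G0, g)
  expected <- outer(G0, exp(-sim$times))
  expect_lt(max(abs(sim$trajectories - expected)), 1e-6)
})

test_that("exact and adaptive integration agree with time modulation on", {
  g <- time_grid()
  set.seed(9)
  for (i in 1:5) {
    M <- matrix(rnorm(25, sd = 0.3), 5, 5)
    diag(M) <- diag(M) - 0.8
    p <- cn_parameters(t(M), runif(5, 0.8, 1.4),
                       c(runif(1, -1, 1) * 1e-5, runif(1, -1, 1) * 5e-4,
                         runif(1, -1, 1) * 1e-2))
    G0 <- runif(5, 0.6, 1.6)
    frozen <- if (i %% 2 == 0) "B" else character(0)
    s1 <- simulate_network(p, G0, g, frozen = frozen, method = "exact")
    s2 <- simulate_network(p, G0, g, frozen = frozen, method = "ode")
    expect_lt(max(abs(s1$trajectories - s2$trajectories)), 1e-5)
  }
})

test_that("knockdown of a cluster in a decoupled network is neutral", {
  g <- time_grid()
  G0 <- c(1.1, 0.9, 1.3, 0.7, 1.2)
  p <- cn_parameters(matrix(0, 5, 5), G0, c(0, 0, 0))
  ref <- cluster_series("MIT", matrix(G0, 5, 7), g)
  for (cl in cluster_labels()) {
    kr <- knockdown_response(p, G0, cl, ref)
    expect_true(kr$stable)
    expect_equal(kr$rms, 0, tolerance = 1e-10)
  }
})

test_that("a positive-feedback motif stabilized by one cluster fails its knockdown screen", {
  # clusters A and B excite each other (unstable pair); cluster C provides
  # the stabilizing inhibition.  Silencing C must blow the system up.
  M <- matrix(0, 5, 5)
  M[1:3, 1:3] <- matrix(c(-1.5, 2, 2,
                          2, -1.5, 2,
                          -2, -2, -1.5), 3, 3)
  M[4, 4] <- -1
  M[5, 5] <- -1
  A <- t(M)
  ev <- eigen(M)$values
  expect_true(all(Re(ev) < 0))  # baseline is stable
  G0 <- c(1, 1, 1, 0.5, 0.5)
  p <- cn_parameters(A, rep(0, 5), c(0, 0, 0))
  base <- simulate_network(p, G0, time_grid())
  expect_false(base$flags$diverged)
  ref <- cluster_series("MIT",
                        base$trajectories[, match(time_grid()$times, base$times)],
                        time_grid())
  kr <- knockdown_response(p, G0, "C", ref)
  expect_false(kr$stable)
  # brute-force oracle: forward-Euler integration with C clamped to zero
  h <- 1e-3
  y <- G0; y[3] <- 0
  Mk <- M; Mk[3, ] <- 0
  for (s in seq_len(28 / h)) y <- y + h * as.numeric(Mk %*% y)
  expect_gt(max(abs(y)), 50 * max(abs(ref$values)))
})

test_that("integrator failure is reported as divergence, not an error", {
  # strongly unstable system: lsoda gives up long before t = 28
  p <- cn_parameters(t(10 * diag(5)), rep(0, 5), c(0, 0, 0))
  sim <- simulate_network(p, rep(1, 5), time_grid(), method = "ode",
                          divergence_bound = 100)
  expect_true(sim$flags$diverged)
})
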