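test_that("weight validation clips, normalizes and rejects degenerate input", {
  expect_equal(unname(validate_weights(c(0.5, 0.5, 0.5, -0.5, 0))),
               c(0.25, 0.25, 0.25, -0.25, 0))
  expect_equal(unname(validate_weights(c(1, 0, 0, 0, 0))), c(1, 0, 0, 0, 0))
  # clipping happens before normalization
  expect_equal(unname(validate_weights(c(3, 0, 0, 0, 0))), c(1, 0, 0, 0, 0))
  expect_equal(unname(validate_weights(c(2, 2, 0, 0, 0))), c(0.5, 0.5, 0, 0, 0))
  expect_error(validate_weights(rep(0, 5)), "all-zero")
  expect_error(validate_weights(c(1, 2, 3)), "length 5")
})

test_that("weight normalization is idempotent and satisfies both constraints", {
  set.seed(42)
  for (i in 1:50) {
    w <- runif(5, -3, 3)
    if (sum(abs(pmin(1, pmax(-1, w)))) == 0) next
    v <- validate_weights(w)
    expect_equal(sum(abs(v)), 1, tolerance = 1e-9)
    expect_true(all(abs(v) <= 1))
    expect_equal(validate_weights(v), v, tolerance = 1e-12)
  }
})

test_that("time grid enforces the sampling-time invariants", {
  g <- time_grid()
  expect_length(g$times, 7)
  expect_identical(g$times[1], 0)
  expect_equal(g$times[2], 1 / 12) # the 2 h sample
  expect_error(time_grid(c(1, 2, 3)), "first")
  expect_error(time_grid(c(0, 3, 2)), "increasing")
  expect_error(time_grid(c(0, 1, 1)), "increasing")
  expect_error(time_grid(c(0, 1), dense_step = -1), "positive")
})

test_that("cluster series preserves A-E label order and rejects bad labels", {
  g <- time_grid()
  m <- matrix(seq_len(35), 5, 7,
              dimnames = list(c("C", "A", "E", "B", "D"), NULL))
  cs <- cluster_series("MIT", m, g)
  expect_identical(rownames(cs$values), cluster_labels())
  expect_equal(unname(cs$values["C", 1]), 1) # row C was first in the input
  m2 <- m
  rownames(m2) <- c("A", "A", "B", "C", "D")
  expect_error(cluster_series("MIT", m2, g), "duplicate")
  expect_error(cluster_series("MIT", m[1:4, ], g), "5 rows")
})

test_that("time-course tables round-trip bit-identically", {
  g <- time_grid()
  set.seed(7)
  cs <- cluster_series("ECM", matrix(rnorm(35, 1, 0.3), 5, 7), g)
  ev <- cell_event_series(rnorm(7), rnorm(7), rnorm(7), g)
  th <- list(thickness = cumsum(abs(rnorm(7, 0.02))), grid = g)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "c.csv"); f2 <- file.path(d, "e.tsv")
  f3 <- file.path(d, "t.csv")
  write_timecourse_table(cs, f1)
  write_timecourse_table(ev, f2)
  write_timecourse_table(th, f3)
  cs2 <- read_timecourse_table(f1, "clusters", network_id = "ECM", grid = g)
  ev2 <- read_timecourse_table(f2, "events", grid = g)
  th2 <- read_timecourse_table(f3, "thickness", grid = g)
  expect_identical(cs2$values, cs$values)
  expect_identical(ev2$mitosis, ev$mitosis)
  expect_identical(th2$thickness, th$thickness)
})

test_that("table reader reports missing times and unknown columns", {
  g <- time_grid()
  d <- withr::local_tempdir()
  f <- file.path(d, "short.csv")
  df <- data.frame(time = g$times[-7], mitosis = 1:6, apoptosis = 1:6,
                   ecm = 1:6)
  utils::write.table(df, f, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(read_timecourse_table(f, "events", grid = g), "28")
  f2 <- file.path(d, "extra.csv")
  df2 <- data.frame(time = g$times, mitosis = 1:7, apoptosis = 1:7,
                    ecm = 1:7, eel = 1:7)
  utils::write.table(df2, f2, sep = ",", row.names = FALSE, quote = FALSE)
  expect_message(read_timecourse_table(f2, "events", grid = g), "eel")
  f3 <- file.path(d, "bad.csv")
  writeLines(c("time,mitosis,apoptosis,ecm", "0,a,1,1"), f3)
  expect_error(read_timecourse_table(f3, "events"), "non-numeric")
})

test_that("therapy specifications enforce the dose and arity limits", {
  expect_silent(therapy_spec(c(C = 0.6)))
  expect_silent(therapy_spec(c(C = 0.97, D = 2.64)))
  expect_error(therapy_spec(c(A = 1, B = 1, C = 1)), "at most two")
  expect_error(therapy_spec(c(A = 3.5)), "\\[0, 3\\]")
  expect_error(therapy_spec(c(A = -0.1)), "\\[0, 3\\]")
  expect_error(therapy_spec(c(Z = 1)), "A..E")
})

test_that("parameter bundles survive a JSON round trip", {
  set.seed(3)
  p <- cn_parameters(matrix(rnorm(25), 5, 5), rnorm(5), rnorm(3) / 10)
  d <- withr::local_tempdir()
  f <- file.path(d, "cn.json")
  save_parameters(p, f)
  p2 <- load_parameters(f)
  expect_equal(p2$A, p$A)
  expect_equal(p2$B, p$B)
  expect_equal(p2$C, p$C)
  hp <- inert_E_model()
  f2 <- file.path(d, "hybrid.json")
  save_parameters(hp, f2)
  hp2 <- load_parameters(f2)
  expect_equal(hp2$scaling$beta_mit, hp$scaling$beta_mit)
  expect_equal(hp2$weights$MIT$w, hp$weights$MIT$w)
  expect_equal(hp2$g0$ECM, hp$g0$ECM)
  expect_equal(hp2$scenario$tau0, hp$scenario$tau0)
})
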