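test_that("distance covariance diagonal matches the classical JC variance", {
  b <- c(0.1, 0.1, 1)
  n <- 300
  S <- distance_covariance(b, n)
  dpair <- c(b[1] + b[2], b[1] + b[3], b[2] + b[3])
  U <- 0.75 * (1 - exp(-4 * dpair / 3))
  classical <- U * (1 - U) / (n * (1 - 4 * U / 3)^2)
  expect_equal(unname(diag(S)), classical, tolerance = 1e-12)
  # positive semidefinite
  expect_true(all(eigen(S, symmetric = TRUE)$values > -1e-15))
})

test_that("distance covariance vanishes as n grows and flags saturation", {
  S1 <- distance_covariance(c(0.1, 0.1, 1), 300)
  S2 <- distance_covariance(c(0.1, 0.1, 1), 3e6)
  expect_true(all(abs(S2) < 1e-4 * max(abs(S1))))
  # deep into saturation the variance of the long-pair distances explodes
  Ssat <- distance_covariance(c(0.1, 0.1, 10), 300)
  expect_gt(Ssat["D_AC", "D_AC"], 1e3 * S1["D_AC", "D_AC"])
})

test_that("covariances match an empirical multinomial experiment", {
  b <- c(0.1, 0.1, 1); n <- 300
  S <- distance_covariance(b, n)
  set.seed(51)
  cts <- simulate_counts_3(b, n = n, reps = 1e5)
  U <- cbind((cts[, 5] + cts[, 3] + cts[, 4]) / n,
             (cts[, 2] + cts[, 4] + cts[, 5]) / n,
             (cts[, 2] + cts[, 3] + cts[, 5]) / n)
  D <- -0.75 * log(1 - 4 * U / 3)
  keep <- apply(is.finite(D), 1, all)
  emp <- stats::cov(D[keep, ])
  # the delta method is first order; at n = 300 the convexity of the log
  # transform inflates the true long-pair variance by several percent
  expect_true(all(abs(emp - S) / pmax(abs(S), 1e-8) < 0.10 |
                    abs(emp - S) < 1e-6))
})

test_that("predicted zero-branch proportion reproduces the printed values", {
  n <- 300
  expect_lt(predict_zero_proportion(c(0.1, 0.1, 0.1), n)$p_zero, 1e-4)
  expect_equal(predict_zero_proportion(c(0.1, 0.1, 0.5), n)$p_zero, 0.0002,
               tolerance = 0.25)
  expect_equal(predict_zero_proportion(c(0.1, 0.1, 1), n)$p_zero, 0.0224,
               tolerance = 0.01)
  expect_equal(predict_zero_proportion(c(0.1, 0.1, 1.25), n)$p_zero, 0.0842,
               tolerance = 0.01)
  expect_equal(predict_zero_proportion(c(0.1, 0.1, 1.5), n)$p_zero, 0.1996,
               tolerance = 0.01)
  expect_equal(predict_zero_proportion(c(0.1, 0.1, 2), n)$p_zero, 0.4930,
               tolerance = 0.01)
})

test_that("the prediction is monotone in the long branch and n-consistent", {
  dC <- c(0.25, 0.5, 1, 1.5, 2, 3)
  p <- vapply(dC, function(x)
    predict_zero_proportion(c(0.1, 0.1, x), 300)$p_zero, numeric(1))
  expect_true(all(diff(p) > 0))
  # at large n and moderate d_C the prediction matches simulation closely
  set.seed(52)
  n <- 1e4
  pred <- predict_zero_proportion(c(0.1, 0.1, 1.5), n)$p_zero
  cts <- simulate_counts_3(c(0.1, 0.1, 1.5), n = n, reps = 4000)
  emp <- mean(apply(cts, 1, function(x) {
    b <- dm_branch_lengths(distance_triple(x)$D)
    any(b[1:2] <= 0)
  }))
  expect_lt(abs(pred - emp), 3 * sqrt(emp * (1 - emp) / 4000) + 0.003)
})

test_that("prediction does not exceed the simulated DM proportion unduly", {
  set.seed(53)
  for (dC in c(1, 1.5, 2)) {
    pred <- predict_zero_proportion(c(0.1, 0.1, dC), 300)$p_zero
    cts <- simulate_counts_3(c(0.1, 0.1, dC), 300, reps = 4000)
    dm <- mean(apply(cts, 1, function(x) {
      pr <- predict_anomalies(distance_triple(x)$D)
      length(pr$zero) > 0
    }))
    expect_lte(pred, dm + 0.01)
  }
})
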