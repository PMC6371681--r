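test_that("numeric ML recovers branch lengths from exact expected counts", {
  p <- pattern_class_probs_3(c(0.1, 0.1, 0.1))
  fit <- numeric_ml_3(round(p * 1e6), seed = 1)
  expect_equal(unname(fit$branches), c(0.1, 0.1, 0.1), tolerance = 1e-3)
  p2 <- pattern_class_probs_3(c(0.3, 0.7, 1.5))
  fit2 <- numeric_ml_3(round(p2 * 1e6), seed = 2)
  expect_equal(unname(fit2$branches), c(0.3, 0.7, 1.5), tolerance = 1e-3)
})

test_that("numeric ML is never beaten by a coarse likelihood grid", {
  set.seed(21)
  for (i in 1:4) {
    cts <- as.vector(rmultinom(1, 300, pattern_class_probs_3(c(0.1, 0.1, 1))))
    fit <- numeric_ml_3(cts)
    expect_gte(fit$loglik,
               oracle_grid_best3(cts, seq(0, 5, length.out = 25)) - 1e-9)
  }
})

test_that("global boundary solutions match the closed forms", {
  g <- global_boundary_solution(c(100, 0, 0, 0, 0))
  expect_equal(unname(g$branches), c(0, 0, 0))
  expect_equal(g$loglik, -100 * log(4))
  g2 <- global_boundary_solution(c(20, 80, 0, 0, 0))
  expect_equal(unname(g2$branches), c(0, 0, Inf))
  expect_equal(g2$loglik, -100 * log(16))
  g3 <- global_boundary_solution(c(70, 30, 0, 0, 0))
  expect_equal(unname(g3$branches), c(0, 0, 0.383119), tolerance = 1e-6)
  # the other orientations
  expect_equal(unname(global_boundary_solution(c(70, 0, 30, 0, 0))$branches),
               c(0, 0.383119, 0), tolerance = 1e-6)
  expect_equal(unname(global_boundary_solution(c(70, 0, 0, 30, 0))$branches),
               c(0.383119, 0, 0), tolerance = 1e-6)
  expect_null(global_boundary_solution(c(70, 10, 10, 10, 0)))
})

test_that("boundary candidates equal the likelihood evaluated at their trees", {
  set.seed(22)
  for (i in 1:30) {
    cts <- as.vector(rmultinom(1, 300, runif(5) + 0.02))
    for (cand in local_boundary_maxima(cts)) {
      expect_equal(cand$loglik, log_likelihood_3(cts, cand$branches),
                   tolerance = 1e-10)
    }
  }
})

test_that("local boundary families reproduce the identified-sum solutions", {
  # n = 100 with 85 B-C matches: branch to A infinite, B-C separation fixed
  cands <- local_boundary_maxima(c(60, 5, 5, 25, 5))
  infA <- Filter(function(x) is.infinite(x$branches[["d_A"]]) &&
                   !all(is.infinite(x$branches)), cands)[[1]]
  expect_equal(infA$branches[["d_B"]] + infA$branches[["d_C"]],
               -0.75 * log(0.8), tolerance = 1e-10)
  expect_true(infA$indeterminate_split)
  # the all-infinite candidate is always present
  ll <- vapply(cands, function(x) x$loglik, numeric(1))
  expect_true(any(abs(ll - (-100 * log(64))) < 1e-10))
  # counts failing every condition leave only the all-infinite point
  only <- local_boundary_maxima(c(5, 20, 20, 20, 35))
  expect_equal(length(only), 1)
  expect_true(all(is.infinite(only[[1]]$branches)))
})

test_that("no numeric restart beats a holding global boundary condition", {
  set.seed(23)
  for (i in 1:100) {
    nxxx <- sample(5:95, 1)
    cts <- c(nxxx, 100 - nxxx, 0, 0, 0)
    g <- global_boundary_solution(cts)
    num <- numeric_ml_3(cts)
    expect_gte(g$loglik, num$loglik - 1e-6)
  }
})

test_that("infinite branches are confirmed analytically", {
  # A and B identical to each other, C saturated against both
  cts <- c(20, 80, 0, 0, 0)
  num <- numeric_ml_3(cts, seed = 3)
  conf <- confirm_infinite(cts, num)
  expect_true(conf$infinite[["d_C"]])
  expect_equal(conf$loglik, -100 * log(16))
  # informative data: numeric optimum strictly beats infinite candidates
  p <- pattern_class_probs_3(c(0.1, 0.1, 0.5))
  num2 <- numeric_ml_3(round(p * 1e5), seed = 4)
  conf2 <- confirm_infinite(round(p * 1e5), num2)
  expect_identical(conf2$provenance, "numeric")
})

test_that("the clock-plane optimum respects the d_A = d_B restriction", {
  p <- pattern_class_probs_3(c(0.1, 0.1, 0.5))
  cp <- clock_plane_solution(round(p * 1e6), seed = 5)
  expect_equal(cp$branches[["d_A"]], cp$branches[["d_B"]])
  expect_equal(cp$branches[["d_A"]], 0.1, tolerance = 1e-3)
  expect_true(cp$symmetric)
  # 2-D grid oracle on the plane
  set.seed(24)
  cts <- as.vector(rmultinom(1, 300, p))
  cp2 <- clock_plane_solution(cts, seed = 6)
  g <- seq(0, 3, length.out = 60)
  best <- max(outer(g, g, Vectorize(function(a, cc)
    log_likelihood_3(cts, c(a, a, cc)))))
  expect_gte(cp2$loglik, best - 1e-9)
  # symmetric counts put the restricted optimum at the centre or an edge
  sym <- c(150, 80, 30, 30, 10)
  cps <- clock_plane_solution(sym, seed = 7)
  full <- fit_ml3(sym, seed = 7)
  pos <- position_on_path(full$branches[["d_A"]], full$branches[["d_B"]])
  expect_true(is.na(pos) || abs(pos - 0.5) < 1e-4 || pos < 1e-4 ||
                pos > 1 - 1e-4)
})

test_that("the combined workflow returns the right provenance and quality", {
  # counts triggering the global boundary
  expect_identical(ml_workflow(c(100, 0, 0, 0, 0))$provenance,
                   "global-boundary")
  # a clear zero-branch prediction resolves analytically
  set.seed(25)
  cts <- as.vector(rmultinom(1, 300, pattern_class_probs_3(c(0.1, 0.1, 2))))
  # find one predicted-zero replicate
  reps <- simulate_counts_3(c(0.1, 0.1, 2), 300, reps = 50, seed = 26)
  found <- FALSE
  for (i in 1:50) {
    pred <- predict_anomalies(distance_triple(reps[i, ])$D)
    wf <- ml_workflow(reps[i, ], seed = 27)
    if (length(pred$zero)) {
      found <- TRUE
      expect_identical(wf$provenance, "local-boundary")
      expect_true(any(wf$zero))
    }
    # workflow never falls below the pure numeric optimum by more than tol
    num <- numeric_ml_3(reps[i, ], seed = 28)
    expect_gte(wf$loglik, num$loglik - 1e-6)
  }
  expect_true(found)
  # no anomaly: numeric provenance
  calm <- ml_workflow(round(pattern_class_probs_3(c(0.1, 0.1, 0.3)) * 300))
  expect_identical(calm$provenance, "numeric")
})

test_that("workflow and fits are deterministic under a fixed seed", {
  cts <- simulate_counts_3(c(0.1, 0.1, 1.5), 300, reps = 1, seed = 30)[1, ]
  a <- ml_workflow(cts, seed = 31)
  b <- ml_workflow(cts, seed = 31)
  expect_identical(a, b)
  f1 <- fit_ml3(cts, seed = 32)
  f2 <- fit_ml3(cts, seed = 32)
  expect_identical(f1, f2)
})

test_that("fitted trees serialise to Newick with explicit boundary lengths", {
  g <- global_boundary_solution(c(20, 80, 0, 0, 0))
  nw <- ml3_newick(g)
  expect_match(nw, "^\\(A:0,B:0,C:9999\\);$")
  d <- c(0.1 / 3, 0.1 / 3, 1, 1, 0.1 / 3)
  fq <- fit_quartet(round(pattern_class_probs_4("13|24", d) * 1e5), seed = 40)
  expect_match(quartet_newick(fq), "^\\(\\(W:.*\\);$")
})

test_that("position_on_path handles ends, symmetry and undefined cases", {
  expect_equal(position_on_path(0, 0.3), 0)
  expect_equal(position_on_path(0.3, 0), 1)
  expect_equal(position_on_path(0.05, 0.05), 0.5)
  expect_true(is.na(position_on_path(0, 0)))
  expect_true(is.na(position_on_path(Inf, 0.1)))
})

test_that("parameter recovery error shrinks at large n", {
  set.seed(33)
  cts <- simulate_counts_3(c(0.1, 0.1, 0.5), n = 1e5, reps = 200)
  err <- vapply(seq_len(200), function(i)
    max(abs(fit_ml3(cts[i, ])$branches - c(0.1, 0.1, 0.5))), numeric(1))
  expect_lt(median(err), 0.01)
})
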