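test_that("jc_same_prob matches the closed form and its limits", {
  expect_equal(jc_same_prob(0), 1)
  expect_equal(jc_same_prob(Inf), 0.25)
  expect_equal(jc_same_prob(0.1), 0.906380, tolerance = 1e-6)
  d <- seq(0, 5, by = 0.25)
  expect_true(all(diff(jc_same_prob(d)) < 0))
  expect_error(jc_same_prob(-0.1), "non-negative")
})

test_that("three-taxon class probabilities match a brute-force enumeration", {
  set.seed(101)
  draws <- c(lapply(1:20, function(i) runif(3, 0, 4)),
             list(c(0, 0, 0), c(Inf, Inf, Inf), c(0, 0.5, Inf),
                  c(Inf, 0.2, 0.2), c(0, 0, 2)))
  for (d in draws) {
    p <- pattern_class_probs_3(d)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(unname(p), oracle_probs3(d), tolerance = 1e-12)
  }
  expect_equal(unname(pattern_class_probs_3(c(0, 0, 0))), c(1, 0, 0, 0, 0))
  expect_equal(unname(pattern_class_probs_3(c(Inf, Inf, Inf))),
               c(1, 3, 3, 3, 6) / 16)
})

test_that("class probabilities respect taxon-relabelling symmetry", {
  d <- c(0.15, 0.7, 2.2)
  p <- pattern_class_probs_3(d)
  # swapping taxa A and B swaps classes xyx and yxx
  q <- pattern_class_probs_3(d[c(2, 1, 3)])
  expect_equal(unname(p[c("xxx", "xxy", "yxx", "xyx", "xyz")]), unname(q))
  # swapping taxa B and C swaps classes xxy and xyx
  r <- pattern_class_probs_3(d[c(1, 3, 2)])
  expect_equal(unname(p[c("xxx", "xyx", "xxy", "yxx", "xyz")]), unname(r))
})

test_that("three-taxon log-likelihood reproduces the boundary closed forms", {
  expect_equal(log_likelihood_3(c(10, 0, 0, 0, 0), c(0, 0, 0)), -10 * log(4))
  expect_equal(log_likelihood_3(c(4, 4, 4, 4, 4), c(Inf, Inf, Inf)),
               -20 * log(64))
  expect_equal(log_likelihood_3(c(5, 15, 0, 0, 0), c(0, 0, Inf)),
               -20 * log(16))
  # impossible data at a boundary
  expect_identical(log_likelihood_3(c(0, 0, 1, 0, 0), c(0, 0, 1)), -Inf)
})

test_that("four-taxon classes are the 15 base-permutation orbits", {
  cls <- pattern_classes_4()
  expect_equal(nrow(cls), 15)
  expect_equal(sum(cls$multiplicity), 256)
  p <- pattern_class_probs_4("13|24", c(0.1, 0.2, 0.3, 0.15, 0.05))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  p0 <- pattern_class_probs_4("12|34", rep(0, 5))
  expect_equal(unname(p0[1]), 1)
})

test_that("four-taxon log-likelihood agrees with 256-pattern brute force", {
  set.seed(202)
  for (i in 1:100) {
    topo <- sample(quartet_topologies(), 1)
    d <- runif(5, 0, 3)
    cts <- as.vector(rmultinom(1, 200, pattern_class_probs_4(topo, d)))
    expect_equal(log_likelihood_4(cts, topo, d), oracle_loglik4(cts, topo, d),
                 tolerance = 1e-10)
  }
  expect_error(log_likelihood_4(rep(1, 15), "12|43", runif(5)), "topology")
})

test_that("four-taxon class frequencies match the sequence simulator", {
  n <- 200000
  d <- c(0.1, 0.2, 1.0, 0.3, 0.1)
  aln <- simulate_alignment(topology = "13|24", lengths = d, n = n, seed = 77)
  obs <- count_patterns(aln) / n
  p <- pattern_class_probs_4("13|24", d)
  z <- (obs - p) / sqrt(p * (1 - p) / n)
  expect_true(all(abs(z) < 4))
})

test_that("count_patterns classifies columns and validates input", {
  aln <- rbind(A = c("A", "A", "A", "C", "G"),
               B = c("A", "A", "C", "A", "T"),
               C = c("A", "C", "A", "A", "A"))
  cts <- count_patterns(aln)
  expect_equal(as.vector(cts), c(1, 1, 1, 1, 1))
  expect_equal(attr(cts, "n"), 5)
  aln_xxy <- rbind(c("A", "A", "A"), c("A", "A", "A"), c("C", "G", "T"))
  expect_equal(as.vector(count_patterns(aln_xxy)), c(0, 3, 0, 0, 0))
  expect_error(count_patterns(rbind(c("A", "-"), c("A", "A"), c("A", "A"))),
               "non-ACGT")
  expect_error(count_patterns(rbind(c("A"), c("A"))), "3 or 4")
  # order of sites is irrelevant and random alignments sum to n
  set.seed(9)
  aln4 <- matrix(sample(c("A", "C", "G", "T"), 4 * 40, replace = TRUE), 4)
  c1 <- count_patterns(aln4)
  c2 <- count_patterns(aln4[, sample(40)])
  expect_identical(c1, c2)
  expect_equal(sum(c1), 40)
})

test_that("marginalising four-taxon counts drops one taxon consistently", {
  set.seed(33)
  aln <- matrix(sample(c("A", "C", "G", "T"), 4 * 500, replace = TRUE), 4)
  c4 <- count_patterns(aln)
  for (dr in 1:4) {
    expect_equal(unname(marginal_counts_3(c4, dr)),
                 unname(count_patterns(aln[-dr, , drop = FALSE])),
                 ignore_attr = TRUE)
  }
})

test_that("FASTA and PHYLIP round-trips preserve the alignment", {
  aln <- simulate_alignment(branches = c(0.1, 0.1, 0.5), n = 60, seed = 12)
  fa <- write_alignment(aln, tempfile(fileext = ".fasta"), "fasta")
  rt <- read_alignment(fa, "fasta")
  expect_equal(unname(rt), unname(aln))
  ph <- write_alignment(aln, tempfile(fileext = ".phy"), "phylip")
  rt2 <- read_alignment(ph, "phylip")
  expect_equal(unname(rt2), unname(aln))
  expect_identical(count_patterns(rt), count_patterns(aln))
})
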