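# Independent oracles used across the test files. These are written from
# first principles (explicit transition matrices, full pattern enumeration)
# and share no code with the package internals they check.

# JC transition matrix for one branch
oracle_jc_matrix <- function(d) {
  q <- if (is.infinite(d)) 0 else exp(-4 * d / 3)
  m <- matrix((1 - q) / 4, 4, 4)
  diag(m) <- (1 + 3 * q) / 4
  m
}

# three-taxon class probabilities by summation over all 64 site patterns
oracle_probs3 <- function(d) {
  MA <- oracle_jc_matrix(d[1]); MB <- oracle_jc_matrix(d[2])
  MC <- oracle_jc_matrix(d[3])
  p <- numeric(5)
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) {
    pr <- sum(0.25 * MA[, a] * MB[, b] * MC[, cc])
    cls <- if (a == b && b == cc) 1 else if (a == b) 2 else if (a == cc) 3
           else if (b == cc) 4 else 5
    p[cls] <- p[cls] + pr
  }
  p
}

# per-pattern probability table for a quartet topology (4x4x4x4 array)
oracle_pattern_probs4 <- function(topo, d) {
  Ms <- lapply(d, oracle_jc_matrix)
  side <- switch(topo, "12|34" = c(0, 0, 1, 1), "13|24" = c(0, 1, 0, 1),
                 "14|23" = c(0, 1, 1, 0))
  pp <- array(0, dim = c(4, 4, 4, 4))
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) for (dd in 1:4) {
    tips <- c(a, b, cc, dd)
    tot <- 0
    for (u in 1:4) for (v in 1:4) {
      nodes <- ifelse(side == 0, u, v)
      pr <- 0.25 * Ms[[5]][u, v]
      for (k in 1:4) pr <- pr * Ms[[k]][nodes[k], tips[k]]
      tot <- tot + pr
    }
    pp[a, b, cc, dd] <- tot
  }
  pp
}

# four-taxon log-likelihood by brute force over the 256 patterns
oracle_loglik4 <- function(cts, topo, d) {
  pp <- oracle_pattern_probs4(topo, d)
  cls <- lbplace:::.pattern_classes4()
  sum(vapply(seq_len(15), function(r) {
    if (cts[r] == 0) return(0)
    rp <- cls$reps[r, ] + 1
    cts[r] * log(pp[rp[1], rp[2], rp[3], rp[4]])
  }, numeric(1)))
}

# best log-likelihood on a coarse branch-length grid (3 taxa)
oracle_grid_best3 <- function(cts, grid = seq(0, 5, length.out = 50)) {
  best <- -Inf
  for (a in grid) for (b in grid) {
    ll <- vapply(grid, function(cc) log_likelihood_3(cts, c(a, b, cc)),
                 numeric(1))
    best <- max(best, max(ll))
  }
  best
}
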