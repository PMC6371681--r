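# Simulation of site data under Jukes-Cantor (and general reversible)
# models on fixed three- and four-taxon trees. Because sites are iid, the
# default path draws pattern-class counts directly from a multinomial over
# the exact class probabilities; a sequence-level simulator is kept for
# general models and end-to-end I/O checks.

#' Simulate three-taxon pattern-count replicates
#'
#' Draws `reps` multinomial samples of size `n` from the exact Jukes-Cantor
#' class probabilities of the given three-taxon tree. This is equivalent in
#' distribution to simulating `n` iid sites and counting patterns, but much
#' faster.
#'
#' @param branches Numeric `(d_A, d_B, d_C)`, `Inf` allowed.
#' @param n Number of sites per replicate.
#' @param reps Number of replicates.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer matrix `reps x 5` of class counts (columns in the order
#'   of [pattern_classes_3()]).
#' @export
#' @examples
#' simulate_counts_3(c(0.1, 0.1, 1), n = 300, reps = 5, seed = 1)
simulate_counts_3 <- function(branches, n, reps = 1, seed = NULL) {
  if (n < 1 || reps < 1) stop("n and reps must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  p <- pattern_class_probs_3(branches)
  out <- t(rmultinom(reps, n, p))
  colnames(out) <- .classes3
  out
}

#' Simulate four-taxon pattern-count replicates
#'
#' @inheritParams simulate_counts_3
#' @param topology One of [quartet_topologies()].
#' @param lengths Five branch lengths (tips 1-4, then internal).
#' @return Integer matrix `reps x 15` of class counts.
#' @export
simulate_counts_4 <- function(topology, lengths, n, reps = 1, seed = NULL) {
  if (n < 1 || reps < 1) stop("n and reps must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  p <- pattern_class_probs_4(topology, lengths)
  out <- t(rmultinom(reps, n, p))
  colnames(out) <- names(p)
  out
}

#' Jukes-Cantor rate matrix
#'
#' @return The 4x4 JC rate matrix scaled to one expected substitution per
#'   unit branch length.
#' @export
jc_rate_matrix <- function() {
  Q <- matrix(1 / 3, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T")))
  diag(Q) <- -1
  Q
}

#' General time-reversible rate matrix
#'
#' Builds a reversible rate matrix from exchangeabilities and stationary
#' base frequencies, scaled to one expected substitution per unit branch
#' length.
#'
#' @param rates Six exchangeabilities in the order AC, AG, AT, CG, CT, GT.
#' @param freqs Stationary base frequencies (A, C, G, T), summing to one.
#' @return 4x4 rate matrix with rows summing to zero.
#' @export
gtr_rate_matrix <- function(rates = rep(1, 6), freqs = rep(0.25, 4)) {
  if (length(rates) != 6 || any(rates < 0)) stop("need 6 non-negative exchangeabilities")
  if (length(freqs) != 4 || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-8)
    stop("freqs must be 4 positive values summing to 1")
  R <- matrix(0, 4, 4)
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    R[idx[k, 1], idx[k, 2]] <- rates[k]
    R[idx[k, 2], idx[k, 1]] <- rates[k]
  }
  Q <- R %*% diag(freqs)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  dimnames(Q) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  Q
}

.check_rate_matrix <- function(Q, freqs) {
  if (!is.matrix(Q) || any(dim(Q) != 4)) stop("rate matrix must be 4x4")
  off <- Q; diag(off) <- 0
  if (any(off < 0) || any(abs(rowSums(Q)) > 1e-8))
    stop("invalid rate matrix: off-diagonals must be >= 0 and rows sum to 0")
  piQ <- diag(freqs) %*% Q
  if (max(abs(piQ - t(piQ))) > 1e-8)
    stop("rate matrix is not reversible with respect to the given frequencies")
  invisible(TRUE)
}

# transition matrix exp(Q d) for a reversible Q, via symmetrised eigen
# decomposition; d = Inf returns the stationary distribution in every row
.transition_matrix <- function(Q, d, freqs) {
  if (is.infinite(d)) return(matrix(freqs, 4, 4, byrow = TRUE))
  sp <- sqrt(freqs)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  P <- diag(1 / sp) %*% e$vectors %*% diag(exp(e$values * d)) %*%
    t(e$vectors) %*% diag(sp)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate a nucleotide alignment on a small tree
#'
#' Site-by-site simulation: the state at one internal node is drawn from the
#' stationary frequencies and propagated along each branch with the model's
#' transition matrix. For three taxa supply `branches`; for four taxa supply
#' `topology` and five `lengths` as in [pattern_class_probs_4()].
#'
#' @param branches Three branch lengths (three-taxon tree), or `NULL`.
#' @param topology,lengths Quartet topology and five branch lengths
#'   (four-taxon tree), or `NULL`.
#' @param n Number of sites.
#' @param Q Rate matrix; defaults to [jc_rate_matrix()].
#' @param freqs Stationary base frequencies.
#' @param seed Optional integer seed.
#' @param tip_names Row names for the returned alignment.
#' @return Character matrix (taxa x sites).
#' @export
simulate_alignment <- function(branches = NULL, topology = NULL,
                               lengths = NULL, n, Q = jc_rate_matrix(),
                               freqs = rep(0.25, 4), seed = NULL,
                               tip_names = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .check_rate_matrix(Q, freqs)
  bases <- c("A", "C", "G", "T")
  # one categorical draw per site from the row of P given by each state
  draw <- function(P, states) {
    u <- runif(length(states))
    out <- integer(length(states))
    for (s in 1:4) {
      idx <- which(states == s)
      if (length(idx))
        out[idx] <- findInterval(u[idx], cumsum(P[s, ])) + 1L
    }
    pmin(out, 4L)
  }
  if (!is.null(branches)) {
    b <- .check_branches3(branches)
    root <- sample.int(4, n, replace = TRUE, prob = freqs)
    tips <- vapply(1:3, function(k)
      draw(.transition_matrix(Q, b[k], freqs), root), integer(n))
    aln <- t(matrix(bases[tips], nrow = n))
    rownames(aln) <- if (is.null(tip_names)) c("A", "B", "C") else tip_names
  } else if (!is.null(topology) && !is.null(lengths)) {
    b <- .check_branches5(lengths)
    side <- .tipnode(topology)
    u <- sample.int(4, n, replace = TRUE, prob = freqs)
    v <- draw(.transition_matrix(Q, b[5], freqs), u)
    tips <- vapply(1:4, function(k) {
      node <- if (side[k] == 0L) u else v
      draw(.transition_matrix(Q, b[k], freqs), node)
    }, integer(n))
    aln <- t(matrix(bases[tips], nrow = n))
    rownames(aln) <- if (is.null(tip_names)) c("t1", "t2", "t3", "t4")
                     else tip_names
  } else stop("supply either 'branches' (3 taxa) or 'topology' and 'lengths' (4 taxa)")
  aln
}

#' Four-taxon study tree with two long branches
#'
#' Builds the quartet used throughout the two-long-branch experiments: taxa
#' W and X are joined by a path of fixed length with the long-branch taxa Y
#' and Z attached at given fractions along it (evenly spaced by default, at
#' 1/3 and 2/3). Tips are ordered (W, X, Y, Z) and the true topology is
#' `"13|24"` (W with Y, X with Z).
#'
#' @param long Length of the branches to Y and Z.
#' @param path Length of the W-X path (default 0.1).
#' @param positions Attachment fractions of Y and Z along the W-X path.
#' @return List with `topology`, `lengths` (W, X, Y, Z, internal) and
#'   `tips`.
#' @export
quartet_tree <- function(long, path = 0.1, positions = c(1 / 3, 2 / 3)) {
  if (path < 0 || any(positions < 0) || any(positions > 1) ||
      positions[2] < positions[1])
    stop("invalid path length or attachment positions")
  list(topology = "13|24",
       lengths = c(W = path * positions[1],
                   X = path * (1 - positions[2]),
                   Y = long, Z = long,
                   internal = path * (positions[2] - positions[1])),
       tips = c("W", "X", "Y", "Z"))
}

#' Pre-registered experiment grids
#'
#' Returns the simulation configurations for the package's named
#' experiments:
#' \describe{
#'   \item{`placement3`}{one long branch: `d_A = d_B = 0.1`,
#'     `d_C` in 0.1, 0.5, 1, 1.25, 1.5, 2; n = 300, 5000 replicates.}
#'   \item{`dm_accuracy`}{`d_A = d_B` in 0.05, 0.1, 0.2, 0.3 crossed with
#'     the `d_C` grid; n = 300, 5000 replicates per cell.}
#'   \item{`zero_proportions`}{same grid as `placement3`, used for the
#'     zero-branch proportion table.}
#'   \item{`lbc`}{four taxa, long branches of length 1.5 on the
#'     [quartet_tree()]; n = 1000, 5000 replicates.}
#'   \item{`lbj`}{four taxa, long-branch lengths from 0.1 to 10;
#'     n = 1000, 2000 replicates per length.}
#' }
#'
#' @param name Experiment name.
#' @return Data frame of configurations, one row per simulation cell.
#' @export
experiment_grid <- function(name) {
  registry <- c("placement3", "dm_accuracy", "zero_proportions", "lbc", "lbj")
  if (!name %in% registry)
    stop("unknown experiment '", name, "'; available: ",
         paste(registry, collapse = ", "))
  d_C <- c(0.1, 0.5, 1, 1.25, 1.5, 2)
  switch(name,
    placement3 = data.frame(d_AB = 0.1, d_C = d_C, n = 300, reps = 5000),
    zero_proportions = data.frame(d_AB = 0.1, d_C = d_C, n = 300, reps = 5000),
    dm_accuracy = {
      g <- expand.grid(d_AB = c(0.05, 0.1, 0.2, 0.3), d_C = d_C)
      g$n <- 300; g$reps <- 5000
      g
    },
    lbc = data.frame(long = 1.5, path = 0.1, n = 1000, reps = 5000),
    lbj = data.frame(long = c(0.1, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 5, 10),
                     path = 0.1, n = 1000, reps = 2000))
}
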