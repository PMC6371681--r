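#' @useDynLib lbplace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim pnorm rmultinom runif setNames cor binom.test
#'   pchisq prop.test
NULL

#' Site-pattern classes for three taxa
#'
#' Under Jukes-Cantor evolution only the equality structure of the bases at a
#' column matters, so the 64 possible three-taxon site patterns collapse into
#' five classes: `xxx` (all equal), `xxy` (A = B), `xyx` (A = C), `yxx`
#' (B = C) and `xyz` (all different). Pattern counts in this class order are
#' the sufficient statistic for every analysis in the package.
#'
#' @return A data frame with columns `class` and `multiplicity` (the number
#'   of concrete nucleotide patterns in each class; multiplicities sum to 64).
#' @export
#' @examples
#' pattern_classes_3()
pattern_classes_3 <- function() {
  data.frame(class = c("xxx", "xxy", "xyx", "yxx", "xyz"),
             multiplicity = c(4L, 12L, 12L, 12L, 24L))
}

.classes3 <- c("xxx", "xxy", "xyx", "yxx", "xyz")

# validate a 3-taxon count vector; returns it as a named numeric vector
.check_counts3 <- function(counts) {
  counts <- unlist(counts, use.names = FALSE)
  if (length(counts) != 5L)
    stop("three-taxon pattern counts must have 5 entries (",
         paste(.classes3, collapse = ", "), ")")
  if (anyNA(counts) || any(counts < 0))
    stop("pattern counts must be non-negative")
  setNames(as.numeric(counts), .classes3)
}

# validate three branch lengths, infinities allowed; returns named numeric
.check_branches3 <- function(branches) {
  branches <- unlist(branches, use.names = FALSE)
  if (length(branches) != 3L)
    stop("expected three branch lengths (d_A, d_B, d_C)")
  if (anyNA(branches) || any(branches < 0))
    stop("branch lengths must be non-negative (Inf allowed)")
  setNames(as.numeric(branches), c("d_A", "d_B", "d_C"))
}

# q = exp(-4 d / 3); q = 0 represents an infinite branch exactly
.q_of <- function(d) ifelse(is.infinite(d), 0, exp(-4 * d / 3))

#' Jukes-Cantor probability that both ends of a branch carry the same base
#'
#' @param d Branch length in expected substitutions per site; may be `Inf`.
#' @return `1/4 + (3/4) exp(-4 d / 3)`, the probability that the states at
#'   the two ends of the branch are identical. Decreases from 1 at `d = 0`
#'   to the stationary value 1/4 as `d` grows.
#' @export
#' @examples
#' jc_same_prob(c(0, 0.1, Inf))
jc_same_prob <- function(d) {
  if (anyNA(d) || any(d < 0)) stop("branch length must be non-negative")
  0.25 + 0.75 * .q_of(d)
}

#' Exact class probabilities on a three-taxon tree
#'
#' Probability of each of the five site-pattern classes on the unrooted
#' three-taxon tree with branch lengths `d_A`, `d_B`, `d_C` meeting at the
#' internal node, obtained by summing the Jukes-Cantor transition
#' probabilities over the internal node state. Infinite branch lengths are
#' handled exactly via the stationary limit.
#'
#' @param branches Numeric vector `(d_A, d_B, d_C)`; entries may be `Inf`.
#' @return Named numeric vector of five probabilities summing to one.
#' @export
#' @examples
#' pattern_class_probs_3(c(0.1, 0.1, 1))
#' pattern_class_probs_3(c(Inf, Inf, Inf))  # stationary mixture
pattern_class_probs_3 <- function(branches) {
  b <- .check_branches3(branches)
  setNames(cpp_probs3(.q_of(b)), .classes3)
}

#' Log-likelihood of three-taxon pattern counts
#'
#' Log-likelihood of the observed site patterns,
#' `sum_r n_r log(p_r / m_r)` where `p_r` is the class probability and
#' `m_r` the class multiplicity (every concrete pattern within a class is
#' equiprobable under Jukes-Cantor). Natural log units; the closed-form
#' boundary values `-n log 4`, `-n log 16`, `-n log 64` are exact. Returns
#' `-Inf` when a class with positive count has probability zero (an
#' impossible boundary tree).
#'
#' @param counts Numeric vector of 5 class counts in the order of
#'   [pattern_classes_3()].
#' @param branches Numeric vector `(d_A, d_B, d_C)`; entries may be `Inf`.
#' @return Log-likelihood (natural log).
#' @export
#' @examples
#' log_likelihood_3(c(10, 0, 0, 0, 0), c(0, 0, 0))  # -10 log 4
log_likelihood_3 <- function(counts, branches) {
  counts <- .check_counts3(counts)
  b <- .check_branches3(branches)
  cpp_loglik3(counts, .q_of(b))
}

# gradient of log_likelihood_3 with respect to branch lengths (internal)
.grad_loglik3 <- function(counts, d) {
  q <- .q_of(d)
  cpp_grad3_q(counts, q) * (-4 / 3) * q
}

#' Mismatch fractions from three-taxon pattern counts
#'
#' Fraction of sites at which each pair of taxa disagrees, computed from the
#' pattern-class counts: taxa A and B differ at `xyx`, `yxx` and `xyz`
#' columns, and analogously for the other pairs.
#'
#' @param counts Numeric vector of 5 class counts.
#' @return Named numeric vector `(U_AB, U_AC, U_BC)`, each in `[0, 1]`.
#' @export
mismatch_fractions <- function(counts) {
  counts <- .check_counts3(counts)
  n <- sum(counts)
  if (n == 0) stop("total site count is zero")
  c(U_AB = (counts[["xyz"]] + counts[["xyx"]] + counts[["yxx"]]) / n,
    U_AC = (counts[["xxy"]] + counts[["yxx"]] + counts[["xyz"]]) / n,
    U_BC = (counts[["xxy"]] + counts[["xyx"]] + counts[["xyz"]]) / n)
}
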