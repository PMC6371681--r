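# Delta-method variance of the distance-based branch-length estimates and
# the normal-approximation prediction of how often a zero-length branch is
# inferred. Pattern counts are multinomial; the mismatch fractions are
# linear in the class frequencies, so their covariance is exact, and the
# Jukes-Cantor log transform is propagated by the delta method.

.M_PAIRS <- rbind(AB = c(0, 0, 1, 1, 1),
                  AC = c(0, 1, 0, 1, 1),
                  BC = c(0, 1, 1, 0, 1))

#' Covariance of the three Jukes-Cantor distance estimates
#'
#' Exact multinomial covariance of the class frequencies at the true tree,
#' mapped to the mismatch fractions (linear) and then to the JC distances
#' by the delta method. Cross-covariances induced by the shared sequences
#' are included; the diagonal reduces to the classical single-distance
#' variance `U (1 - U) / (n (1 - 4U/3)^2)`.
#'
#' @param branches True branch lengths `(d_A, d_B, d_C)`, finite.
#' @param n Sequence length.
#' @return 3x3 covariance matrix of `(D_AB, D_AC, D_BC)` estimates, with a
#'   logical attribute `saturated` marking pairs whose true mismatch
#'   fraction is at or beyond 0.75 (infinite variance; entries `Inf`).
#' @export
distance_covariance <- function(branches, n) {
  b <- .check_branches3(branches)
  if (any(is.infinite(b))) stop("true branch lengths must be finite")
  if (n < 1) stop("n must be at least 1")
  p <- pattern_class_probs_3(b)
  U <- as.vector(.M_PAIRS %*% p)
  Sigma_p <- (diag(p) - outer(p, p)) / n
  Sigma_U <- .M_PAIRS %*% Sigma_p %*% t(.M_PAIRS)
  sat <- U >= 0.75
  g <- ifelse(sat, Inf, 1 / (1 - 4 * U / 3))
  Sigma_D <- diag(g) %*% Sigma_U %*% diag(g)
  dimnames(Sigma_D) <- list(c("D_AB", "D_AC", "D_BC"),
                            c("D_AB", "D_AC", "D_BC"))
  attr(Sigma_D, "saturated") <- setNames(sat, c("AB", "AC", "BC"))
  Sigma_D
}

#' Predicted proportion of trees with a zero-length branch
#'
#' Normal-approximation prediction of how often the distance-based
#' estimates of the two short branches come out at or below zero. The
#' distance covariance at the true tree is propagated through the
#' three-point formulas to the estimators of `d_A` and `d_B`; each tail
#' probability `P(estimate <= 0)` is computed from the normal
#' approximation, and the two are summed (for positive true lengths the
#' two events are essentially mutually exclusive).
#'
#' @inheritParams distance_covariance
#' @return List with the distance covariance (`cov_D`), the variances
#'   `var_dA` and `var_dB`, the tail probabilities `p_zero_A` and
#'   `p_zero_B`, and their sum `p_zero`.
#' @export
#' @examples
#' predict_zero_proportion(c(0.1, 0.1, 1), n = 300)$p_zero
predict_zero_proportion <- function(branches, n) {
  b <- .check_branches3(branches)
  Sigma_D <- distance_covariance(b, n)
  aA <- c(0.5, 0.5, -0.5)
  aB <- c(0.5, -0.5, 0.5)
  vA <- drop(t(aA) %*% Sigma_D %*% aA)
  vB <- drop(t(aB) %*% Sigma_D %*% aB)
  pA <- if (is.finite(vA)) pnorm(0, mean = b[["d_A"]], sd = sqrt(vA)) else NA_real_
  pB <- if (is.finite(vB)) pnorm(0, mean = b[["d_B"]], sd = sqrt(vB)) else NA_real_
  list(cov_D = Sigma_D, var_dA = vA, var_dB = vB,
       p_zero_A = pA, p_zero_B = pB, p_zero = pA + pB)
}
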