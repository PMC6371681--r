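# Distance-matrix analysis for three taxa: Jukes-Cantor pairwise distances,
# the exact three-point fit of three distances to three branches, and the
# triangle-inequality / saturation conditions that predict zero and
# infinite branch lengths on the ML tree.

#' Jukes-Cantor distance from a mismatch fraction
#'
#' @param U Fraction of differing sites between two taxa, in `[0, 1]`.
#' @return `-(3/4) log(1 - 4U/3)`; `Inf` whenever `U >= 0.75` (saturation),
#'   strictly increasing on `[0, 0.75)`.
#' @export
#' @examples
#' jc_distance(c(0, 0.3, 0.75))
jc_distance <- function(U) {
  if (anyNA(U) || any(U < 0) || any(U > 1))
    stop("mismatch fraction must lie in [0, 1]")
  out <- rep(Inf, length(U))
  ok <- U < 0.75
  out[ok] <- -0.75 * log(1 - 4 * U[ok] / 3)
  out
}

#' Pairwise Jukes-Cantor distances from three-taxon counts
#'
#' @param counts Numeric vector of 5 class counts.
#' @return List with `U` (mismatch fractions) and `D` (JC distances), each a
#'   named vector over the pairs AB, AC, BC.
#' @export
distance_triple <- function(counts) {
  U <- mismatch_fractions(counts)
  D <- setNames(jc_distance(U), c("D_AB", "D_AC", "D_BC"))
  list(U = U, D = D)
}

.check_distances <- function(D) {
  D <- unlist(D, use.names = FALSE)
  if (length(D) != 3L) stop("expected three pairwise distances (AB, AC, BC)")
  if (anyNA(D) || any(D < 0)) stop("distances must be non-negative (Inf allowed)")
  setNames(as.numeric(D), c("D_AB", "D_AC", "D_BC"))
}

#' Exact three-point branch lengths from pairwise distances
#'
#' Fits the three pairwise distances exactly to the unrooted three-taxon
#' tree. On three taxa minimum evolution, neighbour joining and least
#' squares all coincide with this fit. Outputs can legitimately be negative
#' (a triangle-inequality violation) or infinite.
#'
#' @param D Numeric vector `(D_AB, D_AC, D_BC)`, `Inf` allowed.
#' @return Named numeric vector `(d_A, d_B, d_C)` with
#'   `d_A = (D_AB + D_AC - D_BC) / 2` and cyclic analogues.
#' @export
#' @examples
#' dm_branch_lengths(c(0.2, 0.3, 0.4))
dm_branch_lengths <- function(D) {
  D <- .check_distances(D)
  c(d_A = (D[["D_AB"]] + D[["D_AC"]] - D[["D_BC"]]) / 2,
    d_B = (D[["D_AB"]] + D[["D_BC"]] - D[["D_AC"]]) / 2,
    d_C = (D[["D_AC"]] + D[["D_BC"]] - D[["D_AB"]]) / 2)
}

#' Predict zero and infinite branch lengths of the ML tree from distances
#'
#' Implements the distance-based decision rules for anomalous ML trees.
#' Infinite-distance rules take precedence: a branch is predicted infinite
#' when both distances involving its taxon are infinite (saturated), and
#' when all three distances are infinite at least two branches must be
#' infinite. Otherwise a branch is predicted to have length zero when the
#' triangle inequality fails for it, i.e. `D_BC >= D_AB + D_AC` predicts
#' `d_A = 0` (and cyclically), including the case of exactly one infinite
#' distance. Ties (`>=` as stated) count as zero predictions.
#'
#' @param D Numeric vector `(D_AB, D_AC, D_BC)`, `Inf` allowed.
#' @return List with components `zero` and `infinite` (character subsets of
#'   `c("A", "B", "C")`) and logical `at_least_two_infinite` (the
#'   all-saturated case, where only "at least two infinite branches" can be
#'   asserted).
#' @export
#' @examples
#' predict_anomalies(c(0.2, 0.5, 0.9))        # d_A = 0
#' predict_anomalies(c(0.3, Inf, Inf))        # d_C = Inf
predict_anomalies <- function(D) {
  D <- .check_distances(D)
  inf <- is.infinite(D)
  res <- list(zero = character(0), infinite = character(0),
              at_least_two_infinite = FALSE)
  if (sum(inf) == 3L) {
    res$at_least_two_infinite <- TRUE
    return(res)
  }
  if (sum(inf) == 2L) {
    # the taxon shared by the two saturated pairs has an infinite branch
    if (inf[["D_AB"]] && inf[["D_AC"]]) res$infinite <- "A"
    else if (inf[["D_AB"]] && inf[["D_BC"]]) res$infinite <- "B"
    else res$infinite <- "C"
    return(res)
  }
  zero <- character(0)
  if (D[["D_BC"]] >= D[["D_AB"]] + D[["D_AC"]]) zero <- c(zero, "A")
  if (D[["D_AC"]] >= D[["D_AB"]] + D[["D_BC"]]) zero <- c(zero, "B")
  if (D[["D_AB"]] >= D[["D_AC"]] + D[["D_BC"]]) zero <- c(zero, "C")
  res$zero <- zero
  res
}
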