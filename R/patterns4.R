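# Four-taxon pattern classes are enumerated programmatically: each of the
# 256 site patterns is reduced to its restricted-growth string (bases
# renamed in order of first appearance), which identifies its orbit under
# the 24 base permutations. There are 15 orbits; multiplicities sum to 256.

.env4 <- new.env(parent = emptyenv())

.pattern_classes4 <- function() {
  if (!is.null(.env4$classes)) return(.env4$classes)
  pats <- as.matrix(expand.grid(rep(list(0:3), 4), KEEP.OUT.ATTRS = FALSE))
  canon <- apply(pats, 1, function(p) {
    first <- unique(p)
    paste(match(p, first) - 1L, collapse = "")
  })
  tab <- table(canon)
  labels <- sort(names(tab))
  reps <- t(vapply(strsplit(labels, ""), function(ch) as.integer(ch),
                   integer(4)))
  letters4 <- c("x", "y", "z", "w")
  names4 <- vapply(seq_along(labels), function(i)
    paste(letters4[reps[i, ] + 1L], collapse = ""), character(1))
  cls <- list(label = labels, name = names4, reps = reps,
              mult = as.numeric(tab[labels]))
  stopifnot(sum(cls$mult) == 256)
  .env4$classes <- cls
  cls
}

#' Site-pattern classes for four taxa
#'
#' The 256 four-taxon site patterns reduce to 15 equivalence classes under
#' Jukes-Cantor evolution (orbits under relabelling of the four bases).
#' Classes are named by the equality structure of the column, e.g. `xxyy`
#' means taxa 1 and 2 share one base and taxa 3 and 4 share another.
#'
#' @return Data frame with columns `class` and `multiplicity`
#'   (multiplicities sum to 256). The row order is the canonical class order
#'   used by all four-taxon count vectors in the package.
#' @export
pattern_classes_4 <- function() {
  cls <- .pattern_classes4()
  data.frame(class = cls$name, multiplicity = as.integer(cls$mult))
}

.check_counts4 <- function(counts) {
  cls <- .pattern_classes4()
  counts <- unlist(counts, use.names = FALSE)
  if (length(counts) != 15L)
    stop("four-taxon pattern counts must have 15 entries")
  if (anyNA(counts) || any(counts < 0))
    stop("pattern counts must be non-negative")
  setNames(as.numeric(counts), cls$name)
}

#' Resolved quartet topologies
#'
#' The three resolved unrooted topologies for four taxa, written as the
#' split of tip indices across the internal branch: `"12|34"`, `"13|24"`,
#' `"14|23"`.
#'
#' @return Character vector of the three topology labels.
#' @export
quartet_topologies <- function() c("12|34", "13|24", "14|23")

# tip -> internal-node assignment (0 = node u, 1 = node v) for a topology
.tipnode <- function(topology) {
  side <- switch(topology,
    "12|34" = c(0L, 0L, 1L, 1L),
    "13|24" = c(0L, 1L, 0L, 1L),
    "14|23" = c(0L, 1L, 1L, 0L),
    stop("unknown topology '", topology, "'; use one of ",
         paste(quartet_topologies(), collapse = ", ")))
  side
}

.check_branches5 <- function(lengths) {
  lengths <- unlist(lengths, use.names = FALSE)
  if (length(lengths) != 5L)
    stop("expected five branch lengths (four tips, then the internal branch)")
  if (anyNA(lengths) || any(lengths < 0))
    stop("branch lengths must be non-negative (Inf allowed)")
  setNames(as.numeric(lengths), c("d_1", "d_2", "d_3", "d_4", "d_int"))
}

#' Exact class probabilities on a four-taxon tree
#'
#' @param topology One of [quartet_topologies()].
#' @param lengths Numeric vector of 5 branch lengths: tips 1-4, then the
#'   internal branch. Entries may be `Inf`.
#' @return Named numeric vector of 15 class probabilities summing to one.
#' @export
pattern_class_probs_4 <- function(topology, lengths) {
  cls <- .pattern_classes4()
  b <- .check_branches5(lengths)
  p <- cpp_probs4(.q_of(b), cls$reps, cls$mult, .tipnode(topology))
  setNames(p, cls$name)
}

#' Log-likelihood of four-taxon pattern counts
#'
#' Log-likelihood of the observed site patterns of a four-taxon alignment
#' on a resolved quartet topology, computed by summing over the two
#' internal node states. As in [log_likelihood_3()], class counts
#' contribute per-pattern probabilities (class probability over class
#' multiplicity).
#'
#' @inheritParams pattern_class_probs_4
#' @param counts Numeric vector of 15 class counts in the order of
#'   [pattern_classes_4()].
#' @return Log-likelihood (natural log).
#' @export
log_likelihood_4 <- function(counts, topology, lengths) {
  cls <- .pattern_classes4()
  counts <- .check_counts4(counts)
  b <- .check_branches5(lengths)
  cpp_loglik4(counts, .q_of(b), cls$reps, cls$mult, .tipnode(topology))
}

.grad_loglik4 <- function(counts, topology, d) {
  cls <- .pattern_classes4()
  q <- .q_of(d)
  cpp_grad4_q(counts, q, cls$reps, cls$mult, .tipnode(topology)) * (-4 / 3) * q
}

# map the 15 four-taxon classes onto the 5 three-taxon classes obtained by
# dropping one tip; well defined because base relabelling commutes with
# dropping a coordinate
.marginal_map4 <- function(drop) {
  cls <- .pattern_classes4()
  keep <- setdiff(1:4, drop)
  vapply(seq_along(cls$name), function(i) {
    p <- cls$reps[i, keep]
    if (p[1] == p[2] && p[2] == p[3]) return(1L)      # xxx
    if (p[1] == p[2]) return(2L)                      # xxy
    if (p[1] == p[3]) return(3L)                      # xyx
    if (p[2] == p[3]) return(4L)                      # yxx
    5L                                                # xyz
  }, integer(1))
}

#' Marginal three-taxon counts from four-taxon counts
#'
#' Collapses a 15-class four-taxon count vector onto the 5-class counts of
#' the sub-alignment obtained by dropping one taxon. Each four-taxon class
#' maps to a single three-taxon class, so no information beyond the class
#' reduction is lost.
#'
#' @param counts Numeric vector of 15 four-taxon class counts.
#' @param drop Index (1-4) of the taxon to drop; the remaining taxa keep
#'   their relative order.
#' @return Named numeric vector of 5 three-taxon class counts.
#' @export
marginal_counts_3 <- function(counts, drop) {
  counts <- .check_counts4(counts)
  map <- .marginal_map4(drop)
  out <- numeric(5)
  for (i in seq_along(counts)) out[map[i]] <- out[map[i]] + counts[i]
  setNames(out, .classes3)
}
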