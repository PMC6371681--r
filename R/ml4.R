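# Maximum likelihood for four-taxon trees: each of the three resolved
# topologies is optimised separately (bounded multi-start quasi-Newton over
# the five branch lengths) and the winner taken, as is standard for
# exhaustive small-tree searches.

# as for three taxa, the search runs over q = exp(-4 d / 3) in [0, 1] so
# the saturated region is not an infinite plateau and the boundary optima
# (zero / infinite branches) are exact
.optim_ml4 <- function(counts, topology, start) {
  cls <- .pattern_classes4()
  tn <- .tipnode(topology)
  fn <- function(qv) -cpp_loglik4(counts, qv, cls$reps, cls$mult, tn, TRUE)
  gr <- function(qv) -cpp_grad4_q(counts, qv, cls$reps, cls$mult, tn)
  optim(exp(-4 * start / 3), fn, gr, method = "L-BFGS-B", lower = 0,
        upper = 1, control = list(maxit = 300))
}

# multi-start fit of one topology
.fit_topology4 <- function(counts, topology, restarts) {
  starts <- matrix(rep(0.1, 5), nrow = 1)
  if (restarts > 1)
    starts <- rbind(starts,
                    matrix(exp(runif(5 * (restarts - 1), log(1e-3), log(5))),
                           ncol = 5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(.optim_ml4(counts, topology, starts[i, ]),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || -fit$value > best$loglik))
      best <- list(lengths = setNames(.d_of_q(fit$par),
                                      c("d_1", "d_2", "d_3", "d_4", "d_int")),
                   loglik = -fit$value)
  }
  if (is.null(best)) stop("all restarts failed for topology ", topology)
  best
}

#' Maximum-likelihood quartet fit
#'
#' Fits all three resolved quartet topologies by bounded multi-start
#' numeric search and selects the one with the highest log-likelihood.
#' Log-likelihood ties (within `tie_tol`) are broken by the fixed topology
#' order `"12|34"`, `"13|24"`, `"14|23"` and flagged.
#'
#' @param counts Numeric vector of 15 four-taxon class counts.
#' @param restarts Number of starting points per topology (default 5).
#' @param seed Optional integer seed for the random starts.
#' @param tie_tol Log-likelihood difference below which topologies are
#'   reported as tied.
#' @return A `quartet_fit`: per-topology fits (`fits`), the winning
#'   `topology`, its `lengths` and `loglik`, and a `tie` flag.
#' @export
fit_quartet <- function(counts, restarts = 5, seed = NULL,
                        tie_tol = 1e-9) {
  counts <- .check_counts4(counts)
  if (!is.null(seed)) set.seed(seed)
  topos <- quartet_topologies()
  fits <- lapply(topos, function(tp)
    .fit_topology4(counts, tp, restarts))
  names(fits) <- topos
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  win <- which.max(ll)
  tie <- sum(ll >= ll[win] - tie_tol) > 1L
  if (tie) win <- which(ll >= ll[win] - tie_tol)[1]
  structure(list(fits = fits, topology = topos[win],
                 lengths = fits[[win]]$lengths, loglik = ll[win],
                 loglik_all = ll, tie = tie, n_restarts = restarts),
            class = "quartet_fit")
}

#' @export
print.quartet_fit <- function(x, ...) {
  cat("Quartet ML fit: winning topology", x$topology,
      if (x$tie) "(tie)" else "", "\n")
  cat("  log-likelihoods:",
      paste(names(x$loglik_all), format(x$loglik_all, digits = 10),
            collapse = "  "), "\n")
  cat("  lengths:", paste(names(x$lengths),
                          format(x$lengths, digits = 4), collapse = "  "),
      "\n")
  invisible(x)
}

#' Classify a quartet fit into the two-long-branch outcome labels
#'
#' For the study tree of [quartet_tree()] (tips W, X, Y, Z with long
#' branches to Y and Z), the fitted quartet falls into one of four
#' outcomes: `"c"` the correct topology (Y with W, Z with X), `"e"` the
#' swapped topology (Z with W, Y with X), `"d"` the long branches joined
#' (Y with Z), and `"f"` the star tree (winning topology with internal
#' branch length zero, where all three topologies coincide; log-likelihood
#' ties are classified here too).
#'
#' @param fit A `quartet_fit` for counts with tip order (W, X, Y, Z).
#' @param zero_tol Internal branch lengths at or below this are treated as
#'   zero.
#' @return One of `"c"`, `"d"`, `"e"`, `"f"`.
#' @export
classify_quartet <- function(fit, zero_tol = 0) {
  if (fit$tie || fit$lengths[["d_int"]] <= zero_tol) return("f")
  switch(fit$topology, "13|24" = "c", "14|23" = "e", "12|34" = "d")
}

#' Attachment positions of the long-branch taxa on the W-X path
#'
#' For a fitted quartet with tip order (W, X, Y, Z), computes where the
#' branches to Y and Z attach along the W-X path, as fractions of the path
#' length (0 at W, 1 at X). On the joined topology (Y with Z) both attach
#' at the same point. The signed separation `z - y` is the four-taxon
#' analogue of the three-taxon relative position.
#'
#' @param fit A `quartet_fit` for counts with tip order (W, X, Y, Z).
#' @return List with `y`, `z` (attachment fractions) and `separation`
#'   (`z - y`); `NA` when the W-X path has length zero or contains an
#'   infinite branch.
#' @export
quartet_positions <- function(fit) {
  b <- fit$lengths
  topo <- fit$topology
  if (topo == "12|34") {
    path <- b[["d_1"]] + b[["d_2"]]
    pos <- if (path > 0 && is.finite(path)) b[["d_1"]] / path else NA_real_
    return(list(y = pos, z = pos, separation = 0))
  }
  path <- b[["d_1"]] + b[["d_int"]] + b[["d_2"]]
  if (path <= 0 || !is.finite(path))
    return(list(y = NA_real_, z = NA_real_, separation = NA_real_))
  at_u <- b[["d_1"]] / path
  at_v <- (b[["d_1"]] + b[["d_int"]]) / path
  if (topo == "13|24") list(y = at_u, z = at_v, separation = at_v - at_u)
  else list(y = at_v, z = at_u, separation = at_u - at_v)
}

#' Write a fitted quartet as Newick
#'
#' @param fit A `quartet_fit`.
#' @param tips Tip labels in count order.
#' @param inf_sentinel Branch length used to encode infinite branches.
#' @return A Newick string for the winning topology; zero-length branches
#'   are printed as exact zeros and infinite branches carry the sentinel.
#' @export
quartet_newick <- function(fit, tips = c("W", "X", "Y", "Z"),
                           inf_sentinel = 9999) {
  b <- fit$lengths
  b[is.infinite(b)] <- inf_sentinel
  side <- .tipnode(fit$topology)
  u <- which(side == 0L); v <- which(side == 1L)
  sprintf("((%s:%g,%s:%g):%g,%s:%g,%s:%g);",
          tips[u[1]], b[u[1]], tips[u[2]], b[u[2]], b[[5]],
          tips[v[1]], b[v[1]], tips[v[2]], b[v[2]])
}
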