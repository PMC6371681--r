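# Maximum-likelihood branch lengths for the three-taxon tree: bounded
# multi-start quasi-Newton search, closed-form optima on the boundaries of
# the solution space (branch lengths 0 or infinity), the molecular-clock
# plane d_A = d_B, analytic confirmation of infinite branches, and the
# combined distance-matrix / ML workflow.

.new_ml3 <- function(branches, loglik, provenance, n_restarts = 0L,
                     indeterminate_split = FALSE) {
  b <- setNames(as.numeric(branches), c("d_A", "d_B", "d_C"))
  structure(list(branches = b, loglik = loglik, provenance = provenance,
                 zero = b == 0, infinite = is.infinite(b),
                 indeterminate_split = indeterminate_split,
                 n_restarts = n_restarts),
            class = "ml3_result")
}

#' @export
print.ml3_result <- function(x, ...) {
  b <- format(x$branches, digits = 6)
  cat("Three-taxon ML fit (", x$provenance, ")\n", sep = "")
  cat("  d_A =", b[1], " d_B =", b[2], " d_C =", b[3], "\n")
  if (x$indeterminate_split)
    cat("  note: only the sum of the two finite branches is identified\n")
  cat("  log-likelihood:", format(x$loglik, digits = 10), "\n")
  invisible(x)
}

# log-likelihood contribution of one pair of taxa at JC separation s, given
# m matching sites out of n: m log s_prob + (n - m) log(per-base mismatch);
# maximised over s this is m log(m/n) + (n-m) log((1-m/n)/3) when m > n/4,
# and -n log 4 at s = Inf otherwise
.pair_loglik_max <- function(m, n) {
  if (m > n / 4) {
    ll <- m * log(m / n)
    if (m < n) ll <- ll + (n - m) * log((1 - m / n) / 3)
    ll
  } else -n * log(4)
}

# JC separation maximising the pair likelihood (Inf when saturated)
.pair_jc <- function(m, n) {
  if (m > n / 4) jc_distance(1 - m / n) else Inf
}

#' Closed-form global maxima on the boundary of the solution space
#'
#' Detects the count configurations for which the global ML solution is
#' known in closed form: all sites constant gives `(0, 0, 0)` with
#' log-likelihood `-n log 4`; when the only mismatch class present is the
#' one separating a single taxon from the two others (e.g. only `xxy`
#' besides `xxx`), the two branches on the identical pair are 0 and the
#' remaining branch is either infinite (log-likelihood `-n log 16`, when
#' `n_xxx <= n/4`) or the Jukes-Cantor estimate from its match fraction.
#'
#' @param counts Numeric vector of 5 class counts.
#' @return An `ml3_result`, or `NULL` when no global boundary condition
#'   applies.
#' @export
global_boundary_solution <- function(counts) {
  counts <- .check_counts3(counts)
  n <- sum(counts)
  if (n == 0) stop("total site count is zero")
  if (counts[["xxx"]] == n)
    return(.new_ml3(c(0, 0, 0), -n * log(4), "global-boundary"))
  nxxx <- counts[["xxx"]]
  sol <- NULL
  if (counts[["xyz"]] == 0 && counts[["xyx"]] == 0 && counts[["yxx"]] == 0)
    sol <- c(0, 0, NA)           # A and B identical; free branch to C
  else if (counts[["xyz"]] == 0 && counts[["yxx"]] == 0 && counts[["xxy"]] == 0)
    sol <- c(0, NA, 0)           # A and C identical; free branch to B
  else if (counts[["xyz"]] == 0 && counts[["xxy"]] == 0 && counts[["xyx"]] == 0)
    sol <- c(NA, 0, 0)           # B and C identical; free branch to A
  if (is.null(sol)) return(NULL)
  free <- .pair_jc(nxxx, n)
  sol[is.na(sol)] <- free
  ll <- -n * log(4) + .pair_loglik_max(nxxx, n)
  .new_ml3(sol, ll, "global-boundary")
}

# constrained optimum on the plane where branch `zero` has length 0: the
# likelihood factorises into two pairwise comparisons against the taxon
# sitting at the internal node
.zero_plane_solution <- function(counts, zero) {
  n <- sum(counts)
  mAB <- counts[["xxx"]] + counts[["xxy"]]
  mAC <- counts[["xxx"]] + counts[["xyx"]]
  mBC <- counts[["xxx"]] + counts[["yxx"]]
  m <- switch(zero, A = c(mAB, mAC), B = c(mAB, mBC), C = c(mAC, mBC))
  est <- c(.pair_jc(m[1], n), .pair_jc(m[2], n))
  ll <- -n * log(4) + .pair_loglik_max(m[1], n) + .pair_loglik_max(m[2], n)
  b <- switch(zero, A = c(0, est[1], est[2]), B = c(est[1], 0, est[2]),
              C = c(est[1], est[2], 0))
  .new_ml3(b, ll, "local-boundary")
}

# constrained optimum with branch `inf` infinite: that taxon decouples and
# only the path length between the two remaining taxa is identified
.infinite_plane_solution <- function(counts, inf) {
  n <- sum(counts)
  m <- switch(inf,
    A = counts[["xxx"]] + counts[["yxx"]],   # B-C matches
    B = counts[["xxx"]] + counts[["xyx"]],   # A-C matches
    C = counts[["xxx"]] + counts[["xxy"]])   # A-B matches
  s <- .pair_jc(m, n)
  ll <- -2 * n * log(4) + .pair_loglik_max(m, n)
  half <- if (is.infinite(s)) Inf else s / 2
  b <- switch(inf, A = c(Inf, half, half), B = c(half, Inf, half),
              C = c(half, half, Inf))
  .new_ml3(b, ll, "local-boundary", indeterminate_split = is.finite(s))
}

#' Closed-form local maxima on the boundaries of the solution space
#'
#' Enumerates the families of boundary optima of the three-taxon
#' log-likelihood:
#' one-branch-zero planes (returned when both pairwise match fractions
#' against the collapsed taxon exceed 1/4, so both remaining estimates are
#' finite), one-branch-infinite planes (where only the sum of the two
#' remaining branch lengths is identified; the returned lengths split the
#' sum evenly and are flagged), and the all-infinite point with
#' log-likelihood `-n log 64`.
#'
#' @param counts Numeric vector of 5 class counts.
#' @return List of `ml3_result` candidates, each with its log-likelihood.
#' @export
local_boundary_maxima <- function(counts) {
  counts <- .check_counts3(counts)
  n <- sum(counts)
  if (n == 0) stop("total site count is zero")
  mAB <- counts[["xxx"]] + counts[["xxy"]]
  mAC <- counts[["xxx"]] + counts[["xyx"]]
  mBC <- counts[["xxx"]] + counts[["yxx"]]
  out <- list()
  if (mAB > n / 4 && mAC > n / 4)
    out <- c(out, list(.zero_plane_solution(counts, "A")))
  if (mAB > n / 4 && mBC > n / 4)
    out <- c(out, list(.zero_plane_solution(counts, "B")))
  if (mAC > n / 4 && mBC > n / 4)
    out <- c(out, list(.zero_plane_solution(counts, "C")))
  if (mBC > n / 4) out <- c(out, list(.infinite_plane_solution(counts, "A")))
  if (mAC > n / 4) out <- c(out, list(.infinite_plane_solution(counts, "B")))
  if (mAB > n / 4) out <- c(out, list(.infinite_plane_solution(counts, "C")))
  c(out, list(.new_ml3(c(Inf, Inf, Inf), -n * log(64), "local-boundary")))
}

# One bounded quasi-Newton run from a given start (in branch lengths).
# The search runs in the transformed variable q = exp(-4 d / 3) on [0, 1],
# where the likelihood is polynomial: this removes the saturation plateau
# that stalls optimizers in branch-length space, and makes both boundary
# optima exactly representable (q = 1 is a zero branch, q = 0 an infinite
# one).
.optim_ml3 <- function(counts, start) {
  fn <- function(qv) -cpp_loglik3(counts, qv, TRUE)
  gr <- function(qv) -cpp_grad3_q(counts, qv)
  optim(exp(-4 * start / 3), fn, gr, method = "L-BFGS-B", lower = 0,
        upper = 1, control = list(maxit = 200))
}

.d_of_q <- function(q) {
  out <- rep(Inf, length(q))
  pos <- q > 0
  out[pos] <- -0.75 * log(q[pos])
  pmax(out, 0)
}

#' Multi-start numeric maximum likelihood for the three-taxon tree
#'
#' Maximises the three-taxon log-likelihood by bounded quasi-Newton search
#' from several starting points: `(0.1, 0.1, 0.1)`, the distance-based
#' three-point estimate (clamped to the interior; the standard
#' initialisation for likelihood searches), and log-uniform draws in
#' `[1e-3, 5]` substitutions per site. Internally the search runs over
#' `q = exp(-4 d / 3)` in `[0, 1]`, so zero branches (`q = 1`) and
#' infinite branches (`q = 0`) are exact boundary solutions rather than
#' capped approximations. Infinite branches found numerically should still
#' be confirmed against the closed-form candidates with
#' [confirm_infinite()].
#'
#' @param counts Numeric vector of 5 class counts.
#' @param restarts Number of starting points (default 5).
#' @param seed Optional integer seed for the random starts.
#' @return An `ml3_result` with provenance `"numeric"`; branches fitted at
#'   the saturation boundary are reported in the `candidate_infinite`
#'   field.
#' @export
numeric_ml_3 <- function(counts, restarts = 5, seed = NULL) {
  counts <- .check_counts3(counts)
  if (sum(counts) == 0) stop("total site count is zero")
  if (restarts < 1) stop("restarts must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  starts <- matrix(rep(0.1, 3), nrow = 1)
  if (restarts > 1) {
    # distance-based start; saturated pairs are pulled just inside
    # saturation so the three-point fit lands in the interior basin
    U <- pmin(mismatch_fractions(counts), 0.74)
    dm <- dm_branch_lengths(jc_distance(U))
    starts <- rbind(starts, pmin(pmax(dm, 1e-3), 10))
  }
  if (restarts > 2)
    starts <- rbind(starts,
                    matrix(exp(runif(3 * (restarts - 2), log(1e-3), log(5))),
                           ncol = 3))
  best <- NULL
  ok <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(.optim_ml3(counts, starts[i, ]), error = function(e) NULL)
    if (is.null(fit)) next
    ok <- TRUE
    if (is.null(best) || -fit$value > best$loglik) {
      best <- list(par = fit$par, loglik = -fit$value)
    }
  }
  if (!ok) stop("all ", restarts, " optimizer restarts failed")
  res <- .new_ml3(.d_of_q(best$par), best$loglik, "numeric",
                  n_restarts = restarts)
  res$candidate_infinite <- best$par <= 0
  res
}

#' Constrained optimum on the molecular-clock plane d_A = d_B
#'
#' Maximises the likelihood under the restriction `d_A = d_B` (two free
#' parameters) by bounded numeric search. When the data are symmetric
#' (`n_xyx = n_yxx`) this restricted optimum is a stationary point of the
#' full likelihood and corresponds to the central peak of the placement
#' distribution; the symmetry is reported in the `symmetric` field.
#'
#' @inheritParams numeric_ml_3
#' @return An `ml3_result` with provenance `"clock-plane"`.
#' @export
clock_plane_solution <- function(counts, restarts = 5, seed = NULL) {
  counts <- .check_counts3(counts)
  if (!is.null(seed)) set.seed(seed)
  fn <- function(p) -cpp_loglik3(counts, c(p[1], p[1], p[2]), TRUE)
  gr <- function(p) {
    g <- cpp_grad3_q(counts, c(p[1], p[1], p[2]))
    -c(g[1] + g[2], g[3])
  }
  starts <- matrix(rep(0.1, 2), nrow = 1)
  if (restarts > 1)
    starts <- rbind(starts,
                    matrix(exp(runif(2 * (restarts - 1), log(1e-3), log(5))),
                           ncol = 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(exp(-4 * starts[i, ] / 3), fn, gr, method = "L-BFGS-B",
            lower = 0, upper = 1, control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || -fit$value > best$loglik))
      best <- list(par = fit$par, loglik = -fit$value)
  }
  if (is.null(best)) stop("clock-plane optimization failed")
  d <- .d_of_q(best$par)
  res <- .new_ml3(c(d[1], d[1], d[2]), best$loglik,
                  "clock-plane", n_restarts = restarts)
  res$symmetric <- counts[["xyx"]] == counts[["yxx"]]
  res
}

#' Confirm infinite branch lengths analytically
#'
#' Compares a numeric fit against the closed-form optima with one or more
#' infinite branches. If some infinite-branch candidate attains a
#' log-likelihood at least as high as the numeric optimum (within `tol`),
#' the candidate is returned: the branch is genuinely infinite and any
#' finite position found numerically is artifactual.
#'
#' @param counts Numeric vector of 5 class counts.
#' @param result An `ml3_result` from [numeric_ml_3()].
#' @param tol Log-likelihood tolerance for declaring the analytic candidate
#'   at least as good (default `1e-6`).
#' @return An `ml3_result`: the best infinite-branch candidate if it is
#'   confirmed, otherwise `result` unchanged.
#' @export
confirm_infinite <- function(counts, result, tol = 1e-6) {
  counts <- .check_counts3(counts)
  cands <- Filter(function(x) any(x$infinite), local_boundary_maxima(counts))
  ll <- vapply(cands, function(x) x$loglik, numeric(1))
  best <- cands[[which.max(ll)]]
  if (best$loglik >= result$loglik - tol) best else result
}

# full reference ML measurement: closed-form global check, then
# multi-start numeric search, then comparison against every closed-form
# boundary optimum (zero planes, infinite planes, all-infinite point).
# The boundary values are exact restricted maxima, so whenever one of them
# attains at least the numeric optimum (within tol) the solution is taken
# to lie on that boundary.
.fit_ml3_full <- function(counts, restarts = 5, tol = 1e-6) {
  g <- global_boundary_solution(counts)
  if (!is.null(g)) return(g)
  num <- numeric_ml_3(counts, restarts = restarts)
  cands <- local_boundary_maxima(counts)
  ll <- vapply(cands, function(x) x$loglik, numeric(1))
  best <- cands[[which.max(ll)]]
  if (best$loglik >= num$loglik - tol) best else num
}

#' Maximum-likelihood fit of a three-taxon tree
#'
#' The package's reference ML procedure: check the closed-form global
#' boundary solutions, otherwise run the multi-start numeric search and
#' confirm candidate infinite branches against the analytic boundary
#' optima.
#'
#' @inheritParams numeric_ml_3
#' @return An `ml3_result`.
#' @export
fit_ml3 <- function(counts, restarts = 5, seed = NULL) {
  counts <- .check_counts3(counts)
  if (!is.null(seed)) set.seed(seed)
  .fit_ml3_full(counts, restarts = restarts)
}

#' Combined distance-matrix / ML workflow
#'
#' The fast solution path for a three-taxon data set: (1) if a closed-form
#' global boundary solution applies, return it; (2) otherwise use the
#' distance-matrix conditions to predict a zero or infinite branch, and when
#' one is predicted return the matching closed-form boundary optimum;
#' (3) otherwise fall back to the multi-start numeric search with analytic
#' confirmation of infinities. The distance-matrix step is a heuristic with
#' measured accuracy; `exhaustive = TRUE` additionally runs the numeric
#' search in step (2) and keeps the better solution.
#'
#' @inheritParams numeric_ml_3
#' @param exhaustive Also run the numeric search when a boundary solution
#'   was predicted, keeping whichever is better.
#' @return An `ml3_result`; the `provenance` field records which path
#'   produced it.
#' @export
ml_workflow <- function(counts, restarts = 5, exhaustive = FALSE,
                        seed = NULL) {
  counts <- .check_counts3(counts)
  if (!is.null(seed)) set.seed(seed)
  g <- global_boundary_solution(counts)
  if (!is.null(g)) return(g)
  pred <- predict_anomalies(distance_triple(counts)$D)
  sol <- NULL
  if (pred$at_least_two_infinite) {
    n <- sum(counts)
    sol <- .new_ml3(c(Inf, Inf, Inf), -n * log(64), "local-boundary")
  } else if (length(pred$infinite)) {
    sol <- .infinite_plane_solution(counts, pred$infinite[1])
  } else if (length(pred$zero)) {
    sol <- .zero_plane_solution(counts, pred$zero[1])
  }
  if (is.null(sol))
    return(confirm_infinite(counts, numeric_ml_3(counts, restarts)))
  if (exhaustive) {
    num <- confirm_infinite(counts, numeric_ml_3(counts, restarts))
    if (num$loglik > sol$loglik) return(num)
  }
  sol
}

#' Position of the third taxon along the A-B path
#'
#' Where the branch to C attaches on the path between A and B, as a
#' fraction: 0 when `d_A = 0` (C at A's end), 1 when `d_B = 0`.
#'
#' @param d_A,d_B Branch lengths to A and B.
#' @return `d_A / (d_A + d_B)`; `NA` when both are zero (no path) or when
#'   either is infinite (no meaningful position).
#' @export
position_on_path <- function(d_A, d_B) {
  out <- d_A / (d_A + d_B)
  out[(d_A == 0 & d_B == 0) | is.infinite(d_A) | is.infinite(d_B)] <- NA_real_
  out
}

#' Write a fitted three-taxon tree as Newick
#'
#' @param result An `ml3_result`.
#' @param tips Tip labels.
#' @param inf_sentinel Branch length used to encode infinite branches.
#' @return A Newick string; infinite branches carry the sentinel length.
#' @export
ml3_newick <- function(result, tips = c("A", "B", "C"), inf_sentinel = 9999) {
  b <- result$branches
  b[is.infinite(b)] <- inf_sentinel
  sprintf("(%s:%g,%s:%g,%s:%g);", tips[1], b[1], tips[2], b[2], tips[3], b[3])
}
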