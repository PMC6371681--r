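---
title: "Placing long branches on small maximum-likelihood trees"
author: "lbplace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placing long branches on small maximum-likelihood trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbplace)
```

## The problem

Maximum likelihood (ML) is consistent under a correctly specified
substitution model, but with finite data it can behave in surprising ways
when a tree contains one or more *long* branches (many expected
substitutions per site). `lbplace` studies this on the smallest possible
trees: the unrooted three-taxon tree, where the only question is where the
branch to the third taxon C attaches along the path between A and B, and
the four-taxon tree, where the three resolved topologies make it possible
to ask whether two long branches "attract" each other.

Everything runs under the Jukes-Cantor (JC) model: equal base frequencies,
equal exchange rates, one parameter (the branch length $d$, in expected
substitutions per site) per branch. Sites are independent and identically
distributed, so an alignment is fully summarised by the counts of its
site-pattern classes: 5 classes for three taxa
($xxx, xxy, xyx, yxx, xyz$, with multiplicities 4, 12, 12, 12, 24 out of
the 64 concrete patterns), and 15 classes for four taxa (enumerated
programmatically as orbits of the 256 patterns under base relabelling;
multiplicities sum to 256). These counts are the sufficient statistic used
by every function in the package.

Two conventions matter throughout:

* **Likelihood scale.** Log-likelihoods are natural-log likelihoods of the
  observed site patterns themselves, i.e. a class with probability $p_r$
  and multiplicity $m_r$ contributes $n_r \log(p_r / m_r)$. On this scale
  the boundary trees have the exact closed-form values $-n\log 4$ (all
  branch lengths zero, identical sequences), $-n\log 16$ (two zero
  branches, one infinite) and $-n\log 64$ (all infinite).
* **Infinite branches are exact.** A branch length of `Inf` is a
  first-class value: transition probabilities use the stationary limit
  exactly, never a numerical cap.

## Maximum likelihood on the three-taxon tree

`fit_ml3()` is the reference fitting procedure. It combines three
ingredients:

1. **Closed-form global optima** (`global_boundary_solution()`). When the
   only mismatch class present separates a single taxon from the two
   others, the ML tree is known exactly: the two branches on the identical
   pair are 0 and the remaining branch is infinite when the constant-site
   fraction is at most 1/4, or the JC distance otherwise.
2. **Multi-start bounded search** (`numeric_ml_3()`). Five starting points
   — $(0.1, 0.1, 0.1)$, the distance-based three-point estimate, and three
   log-uniform draws in $[10^{-3}, 5]$ — each optimised by L-BFGS-B.
   Internally the search runs over $q = e^{-4d/3} \in [0, 1]$ rather than
   $d$ itself: the likelihood is polynomial in $q$, which removes the
   saturation plateau (the likelihood is nearly flat for all large $d$)
   that reliably stalls quasi-Newton searches in branch-length space, and
   it makes both kinds of boundary optimum exactly representable
   ($q = 1$ is a zero branch, $q = 0$ an infinite one). The
   distance-based start matters: without it a few percent of strongly
   saturated replicates converge to the wrong basin.
3. **Exhaustive boundary comparison** (`local_boundary_maxima()`,
   `confirm_infinite()`). On each boundary plane the likelihood
   factorises into pairwise comparisons, so the restricted optima are
   available in closed form: one-branch-zero planes (both remaining
   branches take JC estimates from their match fractions), one-branch-
   infinite planes (the excluded taxon decouples and only the *sum* of the
   two remaining branch lengths is identified — the fit reports an even
   split and flags it), and the all-infinite point. The final answer is
   the numeric optimum unless a boundary candidate attains at least the
   same log-likelihood (tolerance $10^{-6}$); boundary values are exact
   restricted maxima, so classification of zero/infinite branches does not
   depend on the optimizer landing exactly on a bound.

`ml_workflow()` implements the faster combined pipeline: global boundary
check, then the distance-matrix prediction (below) to route directly to
the matching boundary solution, with numeric search as the fallback; an
`exhaustive` flag always runs the numeric search as well and keeps the
better solution.

`clock_plane_solution()` restricts the search to the molecular-clock plane
$d_A = d_B$ (two parameters, same $q$-space machinery). Whether the data
are symmetric ($n_{xyx} = n_{yxx}$) is flagged: symmetric data place the
branch to C exactly at the centre of the A-B path or at an edge, which
explains the central spike of the placement distribution.

## Distance-matrix analysis

Under JC the pairwise distance is $D = -\tfrac34\log(1 - \tfrac43 U)$ for
mismatch fraction $U$, infinite once $U \ge 3/4$ (saturation). On three
taxa all standard distance methods coincide with the exact three-point
fit, `dm_branch_lengths()`, which can return negative branch lengths when
the triangle inequality fails. `predict_anomalies()` turns this into a
decision list used as a predictor of ML behaviour:

* two saturated distances sharing a taxon predict that taxon's branch
  infinite; all three saturated predict "at least two infinite";
* otherwise $D_{BC} \ge D_{AB} + D_{AC}$ (ties included, and including
  exactly one infinite distance) predicts $d_A = 0$, and cyclically.

The infinite rows take precedence over the zero rows, matching the exact
fit (with two saturated distances the zero-branch value is undefined).

## Why zero-length branches appear, and how often

The estimates of the two distances involving a long branch have high
variance, so the sampled distances frequently violate the triangle
inequality, and the exact fit then wants a negative branch — which ML,
constrained to non-negative lengths, turns into a zero. The package
quantifies this with a delta-method calculation
(`distance_covariance()`, `predict_zero_proportion()`): pattern counts
are multinomial, the three mismatch fractions are linear in the class
frequencies (their full $3\times3$ covariance, including the
cross-covariances induced by shared sequences, is computed exactly at the
true tree), the log transform is propagated by the delta method, and the
three-point formulas map distance covariance to the variances of
$\hat d_A$ and $\hat d_B$. Assuming normality, the predicted proportion of
zero-branch trees is $P(\hat d_A \le 0) + P(\hat d_B \le 0)$ — the two
events are mutually exclusive up to a negligible set when the true lengths
are positive, so the sum is the natural combination. Evaluation uses the
true class probabilities, making the prediction a function of the tree and
the sequence length only.

```{r variance}
sapply(c(0.5, 1, 1.25, 1.5, 2), function(dC)
  predict_zero_proportion(c(0.1, 0.1, dC), n = 300)$p_zero)
```

## Simulation

Because sites are iid, the default simulator (`simulate_counts_3()`,
`simulate_counts_4()`) draws pattern-class counts directly from a
multinomial over the exact class probabilities — equivalent in
distribution to site-by-site simulation and far faster. A sequence-level
simulator (`simulate_alignment()`) is retained for general reversible
models (via `gtr_rate_matrix()`; transition matrices from a symmetrised
eigendecomposition) and for end-to-end I/O tests; the two paths are
checked against each other by chi-square goodness of fit. All simulators
accept a seed and are bit-for-bit reproducible.

The study conditions are frozen in `experiment_grid()`: three-taxon trees
with $d_A = d_B \in \{0.05, 0.1, 0.2, 0.3\}$ and
$d_C \in \{0.1, 0.5, 1, 1.25, 1.5, 2\}$ at $n = 300$ sites and 5000
replicates; four-taxon trees with a W-X path of length 0.1, the
long-branch taxa Y and Z attached at 1/3 and 2/3 of the path ("evenly
spaced", so the internal branch is $0.1/3$), $n = 1000$ sites. The
four-taxon replicate counts default to 2000 per length in the
long-branch-joining grid — a compromise that keeps the full grid
affordable while leaving binomial standard errors around one percentage
point.

## The two-long-branch experiments

`run_lbc()` asks whether long branches end up *closer* than they should
be: each replicate is fitted as two three-taxon trees (W, X, Y) and
(W, X, Z) — obtained by exact marginalisation of the 15-class counts —
and as a quartet (`fit_quartet()`, all three topologies, multi-start,
winner by log-likelihood). The relative position of Y and Z along the W-X
path from the three-taxon fits ($x$) is compared with that on the winning
quartet ($y$); closeness would put correct-topology points below the
$x = y$ line, which is tested by an exact binomial sign test (ties
dropped).

`run_lbj()` measures how often the winner joins the two long branches.
Winners are classified as the correct topology (`c`), the swapped one
(`e`), the long-branches-joined one (`d`), or the star (`f`, internal
branch exactly zero, where the three topologies coincide). At strongly
saturated lengths a further degeneracy appears: in a sizeable fraction of
replicates one long-branch estimate is exactly infinite, the taxon
decouples, and all three topologies attain identical likelihoods (ties to
machine precision, confirmed stable under 40 restarts). Such replicates
carry no topology information; any numerical pipeline resolves them by
noise. `run_lbj()` therefore assigns exact ties uniformly at random
(seeded) across the four outcome classes and reports the tie count
separately, so the arbitrariness is visible rather than hidden. With
ties counted as unresolved instead, the joined-topology proportion at
saturation is a few points lower and the star class several points
higher; both views are recoverable from the output.

## Numerical choices

* Optimisation in $q$-space with L-BFGS-B, analytic gradients (C++
  kernels), convergence at the optimizer's default relative tolerance
  ($\sim 10^{-9}$ of the log-likelihood); probabilities are floored at
  $10^{-300}$ inside the objective so impossible boundary configurations
  stay finite during line searches.
* Boundary-vs-numeric comparisons use a $10^{-6}$ log-likelihood
  tolerance, far below the curvature of any simulated optimum.
* Quartet topology ties are declared below $10^{-9}$ log-likelihood
  difference and broken by a fixed topology order in `fit_quartet()`
  (reported via the `tie` flag); the experiment drivers randomise them as
  described above.
* Identical replicate count vectors are fitted once and the result reused
  (counts are sufficient), which speeds the dense grids up substantially.

## What the simulations do and do not show

The generator reproduces the study conditions exactly — iid JC sites on
fixed small trees, no indels, no rate heterogeneity, no model
misspecification. Passing tests therefore say nothing about alignment
error, heterogeneous rates, or real-data model violations; they isolate
the purely statistical behaviour of ML with limited data. The GTR-capable
simulator is provided for exploration but none of the calibrated results
depend on it.

Known limitations: trees with more than four taxa are out of scope; the
variance-based prediction assumes normality of the distance-based branch
estimates and is expected to sit slightly below the simulated zero-branch
proportions (the log transform skews the distribution); and where the
likelihood is exactly flat (decoupled taxa, indeterminate splits of a
fixed path length) the package reports flagged representative values
rather than pretending the parameters are identified.
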