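Package: lbplace
Title: Placement of Long Branches by Maximum Likelihood on Three- and
    Four-Taxon Trees
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how maximum likelihood places long branches
    on the smallest phylogenetic trees under the Jukes-Cantor model. Provides
    exact site-pattern class probabilities and log-likelihoods for three- and
    four-taxon unrooted trees, multinomial and sequence-level simulators,
    analytic boundary solutions of the likelihood (zero and infinite branch
    lengths), distance-matrix conditions that predict those boundary trees,
    a delta-method prediction of the frequency of zero-length branches, and
    experiment drivers for the long-branch-closeness and long-branch-joining
    analyses on four-taxon trees.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
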