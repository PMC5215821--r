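Package: ucatestbed
Title: Simulation Testbed for Phylogenetic Tests of Universal Common Ancestry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate model-selection tests of universal common
    ancestry against an independent-origins alternative. Simulates protein
    sequences under amino-acid replacement models (rtREV, LG) with
    discrete-gamma rate heterogeneity along one or several trees, computes
    phylogenetic likelihoods by Felsenstein pruning with maximum-likelihood
    branch-length and shape estimation, runs the fixed-alignment delta-AIC
    test with and without a progressive multiple-alignment step to expose
    alignment-induced bias, and runs a joint Bayesian coestimation of
    alignment and branch lengths under a TKF91 indel model to compare the
    hypotheses by Bayes factors from harmonic-mean marginal likelihoods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
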