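Package: evotraj
Title: Repeated Cancer Evolution Trajectories and Prognostic Evolutionary Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers repeated cancer evolution trajectories from cross-sectional
    mutation data augmented with per-patient temporal orderings (from cancer
    cell fractions, multi-region or single-cell mutational trees). Patient-level
    orderings are merged into a weighted union graph, resolved into a global
    temporal hierarchy by exact minimum-agony ranking, filtered through Suppes'
    probabilistic-causation conditions (temporal priority and probability
    raising) into a poset, and fitted as a Suppes-Bayes causal network by
    penalized-likelihood hill climbing with cross-validated arc confidence.
    Inferred evolutionary steps can be turned into covariates for regularized
    Cox regression to derive survival-stratifying evolutionary signatures.
    Includes a complete synthetic benchmark generator (cumulative models with
    AND/OR/XOR parent logics, simulated cancer cell fractions, multi-sample
    bulk and single-cell noise models) and structural-accuracy evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    glmnet,
    survival,
    cluster,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    ape
Config/testthat/edition: 3
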