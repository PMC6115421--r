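Package: brainblocks
Title: Weighted Stochastic Block Models for Structural Brain Networks
Version: 0.1.0
Authors@R: person("Maintainer", "Brainblocks", email = "maintainer@brainblocks.dev",
    role = c("aut", "cre"))
Description: Community detection in weighted structural connectomes with the
    weighted stochastic block model (WSBM). Provides variational-Bayes WSBM
    inference with staged assignment priors, consensus community detection
    across repeated fits (variation-of-information centroids, Hungarian label
    alignment, frequency priors), a deterministic spectral-modularity baseline
    with a resolution sweep, generative model evaluation by Kolmogorov-Smirnov
    energy against empirical network statistics, community-conditional node
    statistics (participation, within-module z-score, assortativity,
    versatility, ICC of high-degree node dispersion), block-interaction
    lifespan trend regression with leave-one-out cross-validation and
    permutation inference, and a synthetic bilateral-connectome cohort
    generator with planted block structure and age-modulated trends.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
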