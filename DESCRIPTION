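Package: ndnet
Title: Bayesian Graphical Network Analysis of Neurodevelopmental Traits and
    Depressive Symptoms Across Development
Version: 0.1.0
Authors@R:
    person("ndnet", "maintainers", email = "ndnet@example.org", role = c("aut", "cre"))
Description: A two-cohort pipeline for Bayesian Gaussian graphical model
    analysis of childhood neurodevelopmental traits, social-environmental
    stressors, emotional dysregulation, and depressive symptoms over
    development. Provides multiple imputation by chained equations,
    the shrunken-ECDF nonparanormal transformation, Gibbs sampling of the
    precision matrix under a matrix-F prior calibrated on the partial
    correlation scale, Savage-Dickey Bayes factor classification of edges,
    cross-cohort replication inference, network density and adjacency
    similarity summaries, posterior indices of mediation, Bayesian R2
    predictability, consensus spinglass community detection, and a synthetic
    two-cohort generator with a planted sparse partial-correlation structure
    standing in for access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
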