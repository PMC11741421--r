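Package: strainepi
Title: Strain-Level Association Models for Metagenomic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical models for associating within-species (strain-level)
    variation in shotgun metagenomes with host or environmental phenotypes.
    Provides adaptive k-means coverage filtering of species-stratified gene
    family profiles, per-gene generalized linear models with false discovery
    rate control and a joint regularized-horseshoe alternative, Bayesian
    phylogenetic generalized linear mixed models with leave-one-out predictive
    model comparison via integrated importance sampling, a hierarchical
    random-effects model of within-species pathway carriage, a PERMANOVA
    comparator, and simulation generators for validating all of the above.
    Posterior inference uses a built-in No-U-Turn Hamiltonian Monte Carlo
    sampler implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
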