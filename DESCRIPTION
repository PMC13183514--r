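Package: mixbart
Title: Multilevel Variable Selection with BART-Enhanced Mixed-Effects Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simultaneous selection of individual-level (fixed-effect) and
    cluster-level (random-effect) predictors in hierarchical Gaussian data.
    The fixed-effect surface is modelled by a sum-of-trees (BART) ensemble;
    random effects enter through a modified Cholesky reparameterization of
    their covariance with spike-and-slab priors on the scale parameters,
    fit by a partially collapsed Gibbs sampler. Selection decisions are
    calibrated against within-cluster permutation null distributions of
    BART importance statistics (variable inclusion proportions, within-type
    inclusion proportions, Metropolis importance) and of the lambda
    positivity score over random-effects submodels. Includes a two-step
    procedure for cluster-constant covariates, a sparse Dirichlet
    splitting-prior variant, synthetic-data generators for a factorial
    simulation design, and an experiment runner with sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    lme4
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
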