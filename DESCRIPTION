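Package: occbaci
Title: Hierarchical Occupancy Models for Before-After Control-Impact Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation-based evaluation of hierarchical single-scale and
    multi-scale Bayesian occupancy models under a Before-After Control-Impact
    (BACI) sampling design with imperfect detection. Provides exact
    marginal likelihoods (latent occupancy states summed out analytically),
    an adaptive Metropolis-within-Gibbs sampler with Gelman-Rubin
    diagnostics, synthetic data generators for BACI experiments and for
    terrestrial salamander plot surveys with removal sampling, estimator
    metrics (bias, precision, credible-interval coverage), and a fitting
    interface for plot-level occupancy models with habitat and survey-date
    covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
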