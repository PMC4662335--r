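Package: nestocc
Title: Hierarchical Occupancy Models for Nested Monitoring Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian static and dynamic occupancy models for regional
    monitoring programs with a nested sampling design (wetlands subsampled
    within protected areas, repeat visits within years). Fits an occupancy
    trend model with an among-area random trend and a latitude-on-trend
    effect, and a first-order Markov colonization/persistence model with
    crossed area and year random effects, both with imperfect detection and
    the latent occupancy states marginalized out of the likelihood. Includes
    a synthetic-data generator matching the assumed generative structure,
    an adaptive Metropolis MCMC engine with Gelman-Rubin diagnostics, derived
    area-level and regional annual occupancy (including unsampled years), and
    k-fold cross-validation with predictive deviance for comparing random-
    and fixed-effects formulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
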