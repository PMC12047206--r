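Package: lsmeta
Title: Location-Scale Meta-Analysis and Meta-Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Joint modelling of the mean (location) and the log residual
    standard deviation (scale) of effect sizes in meta-analysis and
    meta-regression. Supports multilevel data (effect sizes nested in
    studies), block-diagonal sampling-error covariance with an assumed
    within-study correlation, phylogenetic and species-level random
    effects in the location part, double-hierarchical models with
    correlated study effects in both parts fitted by adaptive MCMC,
    extended heterogeneity statistics (multilevel I2 and
    coefficient-of-variation style CVH measures), a four-way
    location-scale publication-bias test (small-study effect, decline
    effect, small-study divergence, Proteus effect), and a seeded
    synthetic-data generator for parameter-recovery and operating
    characteristic studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    ape,
    coda,
    jsonlite,
    numDeriv,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
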