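Package: anctrend
Title: Bayesian Hierarchical Trend and Projection Models for Antenatal-Care Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian hierarchical regression models to sparse survey
    estimates of antenatal-care (ANC) coverage among adolescent mothers in
    low- and middle-income countries, on the logit scale with countries nested
    in regions, and projects coverage with 95% credible intervals to 2030.
    Includes a bespoke Metropolis-within-Gibbs sampler with Gelman-Rubin and
    DIC diagnostics, wealth-quintile and urban-rural equity summaries (slope
    index of inequality, coverage gaps, 80%-target flags, rates of change),
    a hierarchical logistic model for individual-level determinants of ANC
    use, sensitivity-analysis harnesses, and a synthetic-data generator that
    emulates the multi-country survey structure with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
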