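Package: shrinksim
Title: Global Shrinkage Factors and Sample Size for Logistic Risk Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study global (uniform) shrinkage of logistic regression
    risk prediction models. Implements the heuristic shrinkage factor of
    van Houwelingen and Le Cessie, the bootstrap uniform shrinkage factor, and
    the optimal shrinkage factor defined as the calibration slope in a large
    validation cohort, together with minimum sample size procedures for model
    development: the analytic criterion that targets the heuristic shrinkage
    factor and a simulation-based search that targets the expected optimal
    shrinkage directly. A Monte-Carlo engine generates random development
    scenarios (multivariate-normal predictors, random coefficients, random
    prevalence and sample size), runs the shrinkage and sample-size studies end
    to end, applies exclusion rules for degenerate scenarios, and summarises
    bias and Monte-Carlo error stratified by the population C-statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    rlang,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
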