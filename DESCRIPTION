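Package: arealex
Title: Small-Area Life Expectancy from Bayesian Spatiotemporal Mortality Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates age-specific death rates and life expectancy for small
    areas with nested geographies (area within district within region) from
    stratified death and population counts. Fits a Bayesian hierarchical
    spatiotemporal Poisson model for log death rates with random-walk age and
    time structure, nested area effects and age-area interactions, using a
    built-in gradient-based MCMC sampler. Converts posterior draws of death
    rates into abridged life tables with Kannisto-Thatcher extension of the
    open-ended old-age group, and summarises life-expectancy levels, trends,
    cross-area inequality gaps, posterior probabilities of change, sex
    comparisons and deprivation gradients. Includes a synthetic-data generator
    with the generative structure the model assumes, data-repair and
    outlier-year interpolation utilities, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
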