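Package: owlbaci
Title: Occupancy Analysis of Forest Owl Responses to Wildfire and
    Invasive Barred Owl Removal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for Before-After-Control-Impact (BACI) analysis of forest
    owl site occupancy under severe wildfire and invasive barred owl removal,
    driven by passive acoustic monitoring. Includes a synthetic-data generator
    emulating a hexagonal acoustic survey grid, calibration of detector
    prediction-score thresholds against a target weekly false-positive rate,
    construction of weekly encounter histories with effort covariates,
    computation of home-range buffer covariates (severe-burn fraction,
    removal overlap, terrain ruggedness, seral forest fraction), Bayesian
    stacked single-season occupancy models with year and site random effects
    fit by an adaptive Metropolis-within-Gibbs sampler over the marginalized
    occupancy likelihood, Gelman-Rubin and MacKenzie-Bailey diagnostics,
    posterior-overlap contrasts, and habitat niche segregation analysis via
    standard ellipses and average marginal effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
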