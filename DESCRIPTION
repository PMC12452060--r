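Package: immunokin
Title: Bayesian Growth Kinetics, Immune Pressure, and Secretome Comparison
    for Syngeneic Tumor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative machinery for functionally comparing transplantable
    syngeneic tumor models across immunocompetent and immunodeficient hosts.
    Fits a log-linear (exponential) tumor growth model to longitudinal caliper
    measurements by random-walk Metropolis Markov chain Monte Carlo, with a
    cohort-shared net growth rate and per-mouse initial bolus sizes; summarises
    immune selective pressure as the posterior log-ratio of growth rates in
    immunodeficient versus immunocompetent hosts; fits the two-parameter
    hyperbolic dose-response model 100*(1 - x/(x + IC50)) to viability plates;
    and calls differentially secreted factors on duplicate-spot antibody
    arrays using a control-derived, abundance-dependent null envelope and
    z-scores. Includes synthetic-data generators that emulate the statistical
    structure of each input so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
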