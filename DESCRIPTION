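Package: bufferguts
Title: Multi-Route Buffered GUTS Survival Models for Terrestrial
    Arthropods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toxicokinetic-toxicodynamic (TKTD) survival modelling for
    above-ground terrestrial arthropods exposed to a chemical through
    several uptake routes (topical contact, acute and chronic feeding).
    Implements the buffered reduced-GUTS state system with
    concentration-addition (CA) and damage-addition (DA) route
    combination and both GUTS death mechanisms, stochastic death (SD)
    and individual tolerance (IT).  Provides exposure-design
    preprocessing for standard honeybee regulatory tests (1-hour
    exposure discretisation, acute-oral dose to food-concentration
    conversion, replicate summation, outlier-test exclusion), a
    multinomial survival likelihood, Bayesian calibration by adaptive
    Markov chain Monte Carlo with a pseudolocal-minimum chain filter,
    maximum-likelihood fitting, model-selection metrics (BIC, NRMSE,
    parameter uncertainty index), a synthetic-data generator for
    honeybee-style test designs, and prediction of combined
    contact-plus-oral validation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
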