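Package: stabkin
Title: Arrhenius-Based Kinetic Modeling for Stability Prediction of
    Biologics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Advanced kinetic modeling for accelerated stability studies of
    biotherapeutics, vaccines and diagnostic reagents. Fits one- and
    two-step Arrhenius-based kinetic models to short-term multi-temperature
    stability data, screens a model catalog by corrected Akaike and Bayesian
    information criteria, propagates fit uncertainty with a multiple-model
    residual bootstrap into predictive bands, and applies the fitted models
    to shelf-life estimation, ICH Q1E baseline comparison, batch-to-batch
    comparison and degradation monitoring under arbitrary temperature
    profiles including cold-chain excursions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
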