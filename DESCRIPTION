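Package: occupipe
Title: Camera-Trap Occupancy Modelling Pipeline with Bayesian Inference and
    Spatial Interpolation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for single-season, single-species occupancy
    analysis of camera-trap surveys in human-dominated landscapes. Generates
    synthetic survey data emulating a 154-site, 21-day trail-camera design;
    builds sites-by-occasions detection histories with effort accounting;
    standardizes site covariates and screens them for collinearity; fits a
    Bayesian occupancy model with constant detection and seven occupancy
    covariates via an adaptive random-walk Metropolis sampler on the
    marginalized likelihood; reports split-chain Rhat, effective sample sizes
    and credible-interval summaries; and interpolates site-level occupancy
    onto a regular grid by inverse distance weighting, written as an ESRI
    ASCII raster.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
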