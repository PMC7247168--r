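Package: nirsel
Title: Wavelength Selection for Near-Infrared Calibration Models
Version: 0.1.0
Authors@R: person("Analytics", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for selecting informative wavelengths in near-infrared
    (NIR) multivariate calibration. Implements the optimal partner wavelength
    combination (OPWC) method, in which every wavelength is scored against
    every other by leave-one-out cross-validated binary linear regression and
    the resulting best-partner mapping is iterated to its stable image set,
    together with moving-window PLS (MW-PLS) and Monte Carlo uninformative
    variable elimination (MC-UVE-PLS) for comparison. Includes a NIPALS PLS1
    engine with leave-one-out cross-validation, evaluation statistics (SECV,
    cross-validated correlation), a Beer-Lambert synthetic spectra generator
    with band-localised components and region-dependent noise, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
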