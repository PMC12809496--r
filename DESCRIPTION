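Package: adxrf
Title: Differentiable Fitting of Energy-Dispersive X-Ray Fluorescence Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and gradient-based fitting of energy-dispersive
    X-ray fluorescence (XRF) spectra. The model spectrum is assembled from
    characteristic emission lines with Hypermet-style step and tail terms,
    Rayleigh and Compton scatter peaks, detector escape peaks and a
    differentiable SNIP continuum estimate. A built-in reverse-mode automatic
    differentiation tape supplies exact gradients of the mean-squared-error
    loss with respect to elemental amplitudes and instrument parameters, so an
    adaptive-moment (Adam-style) optimizer can jointly fit calibration,
    peak-shape, scatter and amplitude parameters without manual tuning.
    Includes fixed-parameter linear per-pixel mapping of raster scans,
    region-of-interest refinement, an end-to-end automated pipeline, and a
    synthetic-data generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
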