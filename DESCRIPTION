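Package: sersmap
Title: Spectral Unmixing and Odor-Source Localization for SERS Gas-Sensor Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for two-dimensional surface-enhanced Raman scattering (SERS)
    gas-sensor arrays: simulation of hyperspectral array scans of odor plumes,
    non-negative matrix factorization (multiplicative updates) of the scan
    matrix into concentration and feature components, heatmap visualization and
    odor-source localization by elliptical two-dimensional Gaussian fitting
    with source-size calibration, and identification of component spectra with
    a small one-dimensional convolutional neural network classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
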