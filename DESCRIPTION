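Package: ldrquant
Title: Calibration and Quantification for a Paper-Based LDR Fluorescence Reader
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts raw analog-to-digital readings from a light-dependent-
    resistor (LDR) fluorescence detector into fluorophore concentrations.
    Implements the voltage-divider conversion from ADC counts to resistance,
    a power-law calibration model relating relative resistance to fluorophore
    concentration, its inverse-variance-weighted nonlinear fit, first-order
    Gaussian propagation of instrument and calibration uncertainties to
    concentration, IUPAC limits of detection and quantification from blank
    statistics, a confident-measurement-range solver, and quantification of
    time-trace measurements. A seeded detector and assay simulator emulates
    the full acquisition chain (LDR response, voltage divider, ADC
    quantization, sensor noise, equilibration lag) so every stage is testable
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
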