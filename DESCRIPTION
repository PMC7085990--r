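Package: petkin
Title: Compartment Modelling and Parametric Imaging for Dynamic PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification of irreversibly binding PET tracers from dynamic
    scans: single- and two-tissue compartment models with a fitted blood-volume
    term, weighted non-linear least-squares fitting with Akaike model
    selection, Patlak graphical analysis, basis-function parametric imaging
    (K1, Ki, Vb, VND plus Patlak Ki and Ve maps), image-derived input
    functions from an aorta region, SUV computation with cutoff calibration
    and confidence intervals, test-retest repeatability statistics
    (Bland-Altman, repeatability coefficient, Deming regression), and a
    synthetic dynamic-PET phantom generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
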