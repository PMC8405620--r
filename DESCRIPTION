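Package: fiberlab
Title: Structural and Mechanical Characterization of Protein Polymer Fibers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis toolkit for microbially produced protein
    fibers. Computes number- and mass-average molecular weights from analytical
    size-exclusion chromatography with an exponential calibration, deconvolves
    the FTIR amide-I band into eleven fixed-center Lorentzians to estimate
    secondary-structure fractions, evaluates polarized-Raman orientation ratios
    normalized to the conformation-insensitive 1450 cm-1 band, analyzes
    wide-angle X-ray fiber diffraction images (sector and azimuthal
    integration, Gaussian peak deconvolution, crystallinity, d-spacings,
    Scherrer crystallite sizes, Herman's orientation function), and extracts
    tensile and cyclic-loading mechanics (modulus, ultimate strength, breaking
    strain by the 90 percent stress-drop rule, toughness, damping capacity and
    damping energy). Every modality ships with a seeded synthetic-data
    generator with attached ground truth so each stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
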