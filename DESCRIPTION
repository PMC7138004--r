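Package: labmu
Title: Top-Down Measurement Uncertainty Estimation for Clinical Laboratories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates measurement uncertainty of clinical laboratory tests
    from routine quality-control data: within-laboratory imprecision from
    internal QC series, and bias from proficiency tests, certified reference
    calibrators and inter-laboratory internal QC scheme peer comparisons.
    Implements the Nordtest, Eurolab and Cofrac bias-uncertainty formulas,
    combines and expands the uncertainty with a coverage factor, judges
    results against Westgard allowable total error and Haeckel-style
    permissible uncertainty limits, and ships a synthetic-data generator
    with known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
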