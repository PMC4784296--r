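Package: qpcrcal
Title: Calibrator-Based Absolute Quantification for Real-Time PCR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts raw per-cycle qPCR fluorescence into absolute starting
    copy numbers using a dilution series of a non-amplified DNA calibrator
    run on the same plate. Per-reaction amplification efficiency is
    estimated from the exponential window of each amplification curve
    (between the take-off point and the second-derivative maximum) and the
    starting amount is back-calculated as pmz = pm / E^n. Includes the
    classical relative-quantification comparators (delta-delta-Cq and the
    Pfaffl ratio with measured efficiencies), a plate simulator with known
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
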