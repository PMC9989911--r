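Package: vitalagree
Title: Agreement Analysis for Wearable Versus Reference Vital-Sign Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validation pipeline for continuous wearable vital-sign monitors
    (photoplethysmography-derived heart rate and respiratory rate) against
    bedside reference monitors. Provides a 1 Hz time-series data model with
    per-sample quality indices, cross-correlation clock synchronization,
    quality filtering and coverage/gap analytics, repeated-measures
    Bland-Altman limits of agreement with MOVER confidence intervals,
    within-threshold agreement, and a Clarke error grid adapted to early-
    warning-score bradycardia/tachycardia thresholds. Includes a synthetic
    paired-cohort generator with closed-form expectations so every stage is
    testable without clinical recordings.
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
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
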