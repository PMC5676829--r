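Package: gazedissect
Title: Gaze Orienting Metrics and Dependent-Correlation Dissociation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for region-of-interest (ROI) eye-tracking
    attention studies: parsing 120 Hz binocular gaze logs with per-eye validity
    codes, fixation detection with a sliding-window distance/velocity filter,
    trial-level quality control (anticipatory looks, sample validity, baseline
    attention checks), latency to first fixation and first-pass dwell time on a
    target ROI, and a statistics layer comparing how two correlated trait
    measures relate to the two attention measures via Pearson and partial
    correlations and Steiger's test for dependent correlations. Includes a
    seeded synthetic-cohort generator that renders complete gaze recordings
    with planted trait-attention couplings, so every stage of the pipeline can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
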