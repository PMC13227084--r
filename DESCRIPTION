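Package: graphomotor
Title: Handwriting Kinematics and Pentagon-Copy Performance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for online (pen-stream) handwriting
    recordings in older-adult cohorts: reading and validating SVC-dialect
    digitizer files, stroke segmentation and extraction of eight kinematic
    features per task (time on air, time down, mean/max pressure, speed and
    acceleration), automated binary scoring of the intersecting-pentagons
    copying test, rule-based Short Physical Performance Battery and
    Timed Up and Go scoring, and covariate-adjusted two-group comparison
    with Benjamini-Hochberg false-discovery-rate control. Includes a seeded
    synthetic cohort generator so the whole pipeline is testable without
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
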