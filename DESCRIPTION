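Package: ppgbp
Title: Assessment Pipeline for PPG- and rPPG-Based Blood Pressure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and audit cuffless blood-pressure prediction
    pipelines from photoplethysmography (PPG) and camera-derived remote PPG
    (rPPG) signals. Provides a seeded synthetic-cohort generator with paired
    PPG and arterial blood pressure (ABP) waveforms, signal windowing under
    fixed-duration and fixed-beat-count strategies, spectral signal-to-noise
    gating, POS remote-pulse extraction, ABP-derived systolic/diastolic
    labelling with plausibility filters, subject-aware (non-mixed) versus
    sample-level (mixed) dataset splits, a compact 1-D neural-network zoo
    trained with early stopping, personalization and final-layer transfer
    protocols, and bin-wise mean-absolute-error evaluation with baseline
    comparison and significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
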