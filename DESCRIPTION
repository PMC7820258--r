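Package: DermaStress
Title: Computational Stress Tests for Image-Based Diagnostic Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Model-agnostic evaluation toolkit for binary image-based
    diagnostic classifiers (melanoma versus nevus triage as the worked
    setting). Provides discrimination metrics with DeLong confidence
    intervals and operating points matched to human-reader benchmarks,
    post-hoc calibration by temperature scaling with RMS calibration
    error, selective-prediction analysis (response-rate-accuracy curves,
    AURRA, gambler's loss and rejection rates), out-of-distribution
    confidence audits, and robustness audits over image-capture variation
    (rotation, flip, brightness, contrast sweeps; replicated-image
    consistency; test-time augmentation). A deterministic synthetic
    lesion-image generator and a toy trainable classifier make the whole
    battery runnable end-to-end without any clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    png,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'calibration.R'
    'prediction.R'
    'transforms.R'
    'synthetic.R'
    'robustness.R'
    'selective.R'
    'discrimination.R'
    'report.R'
    'cli.R'
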