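Package: aaaquant
Title: Abdominal Aortic Aneurysm Boundary Detection and Volume
    Quantification from Cross-Section Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects abdominal aortic aneurysm boundaries and quantifies
    surrogate aneurysm volume from per-slice aortic cross-section
    pixel-count profiles extracted from segmented computed tomographic
    angiography. Provides a sliding-window rule-based boundary detector
    with grid search over its parameters, a rolling-average screen that
    flags segmentation dropout as an anomaly cue, a bidirectional LSTM
    slice labeler with patient-level cross-validation, interval Dice and
    regression-style evaluation metrics, surrogate volume and enlargement
    statistics, and a seeded synthetic profile generator for end-to-end
    testing without imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
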