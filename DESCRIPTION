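Package: kinsway
Title: Classification of Whole-Body Movement and Postural Sway Timeseries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for distinguishing diagnostic groups from markerless
    whole-body kinematics and balance-board postural sway recorded during
    static balance poses. Implements the full analysis pipeline: a synthetic
    cohort simulator with group-dependent movement variability, delimited
    timeseries input/output, cleaning (forward-fill imputation, multilevel
    Haar wavelet denoising, middle trimming, exponential-tail variance
    quality control), sliding-window entropy and variance features, a
    pose-indexed random-forest ensemble with two-level majority voting and a
    continuous boundary-distance score, stratified participant-level
    cross-validation with confusion metrics, and interpretation via
    aggregated mean-decrease-impurity feature rankings, Cohen's d effect
    sizes, and boundary-distance correlations with clinical covariates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
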