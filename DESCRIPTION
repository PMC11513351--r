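Package: hastf
Title: Hybrid Attention Spatio-Temporal Networks for EEG Emotion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Differential-entropy band features, 10-20 montage grid mapping,
    and a hybrid attention network for EEG-based emotion recognition: a
    U-shaped convolutional spatial extractor with parameter-free energy-based
    spatial attention, and a class-token transformer temporal encoder.
    Includes a synthetic EEG generator with planted class-dependent band-power
    effects, subject-dependent 5-fold cross-validation training, ablation
    experiments with one-way ANOVA and Games-Howell post-hoc comparisons, and
    topographic attention-map visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
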