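Package: duetsync
Title: Quantifying Interpersonal Movement Coordination in Duo Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and predicting visually apparent bouts of
    interpersonal coordination between two performers from video-derived
    movement time series. Implements a continuous Morlet wavelet transform and
    cross-wavelet transform with band-restricted energy and phase extraction,
    video region-of-interest barycentre tracking and quantity-of-motion
    estimation, audio envelope features (RMS, wavelet energy, a simplified
    pulse-clarity index), interval-annotation agreement (banded asymmetric
    dynamic time warping plus Cohen's kappa) and multi-rater bout aggregation,
    a twelve-predictor frame-wise feature table, and bout classification with
    logistic regression and random forests evaluated by held-out AUC, DeLong
    comparisons and Youden cutoffs. A coupled-oscillator dyad simulator with
    noisy annotators, click-train and sparse-event audio, and synthetic blob
    videos makes the whole pipeline testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    pROC,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
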