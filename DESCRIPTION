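Package: gaitverify
Title: Validation of Markerless Motion Capture for Gait Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for validating multi-camera markerless
    motion capture (pose estimation plus depth) against marker-based motion
    capture for treadmill gait. Provides a synthetic multi-camera gait
    generator with known ground truth and configurable error mechanisms
    (joint-center offsets, depth-surface bias, keypoint noise, dropout),
    direct kinematics from COCO-17 keypoints (camera-to-world transform,
    confidence-weighted fusion, zero-phase Butterworth filtering, vector-based
    hip and knee flexion angles), gait-cycle segmentation from minimum knee
    flexion or vertical ground-reaction-force heel strikes with 0-100%
    time normalization, and a method-agreement toolbox: waveform RMSE,
    Lin's concordance correlation with Fisher-z confidence intervals,
    Pearson correlation, Bland-Altman limits of agreement, ICC(2,1) with
    F-based confidence intervals, SEM, MDC, and mean-waveform offset
    correction. Results are tidy tibbles with broom-style tidy() and
    glance() methods and ggplot2 autoplot() figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
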