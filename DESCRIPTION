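Package: pupilgram
Title: Pupillometry Pupil Tracking, Shape Metrics and Method-Agreement Analysis for Rodent Eye Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the pupil of a rodent eye through a video recording and turns it
    into a pupillogram (pupil diameter against time). Implements a classical
    adaptive-threshold frame-to-frame pupil tracker initialised from a single
    bounding box, per-frame binary-mask shape metrics (area, centroid,
    chain-code perimeter, circularity, maximum Feret diameter), segmentation
    quality metrics (pixel accuracy, mean accuracy, IoU, mIoU, MAPE), and
    Bland-Altman method-agreement statistics with rank correlations and
    regression. A deterministic synthetic eye-video generator with per-frame
    ground-truth masks makes the whole pipeline testable end to end without
    recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
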