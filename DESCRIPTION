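Package: skillflow
Title: Surgical Skill Classification from Sparse Optical Flow of Endoscopic Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for video-based assessment of surgical
    skill in minimally invasive surgery training. Two tool regions of an
    endoscopic video are seeded with Shi-Tomasi corners and tracked with
    pyramidal Lucas-Kanade sparse optical flow, yielding a 240-feature
    per-frame time series (positions and per-frame displacements of 30
    points per tool). Sliding windows over these series are classified
    into novice/intermediate/expert by a benchmark of six methods (1-D
    CNN, LSTM, CNN+LSTM, residual network, convolutional autoencoder with
    an SVM head, and DFT/DCT frequency-peak features with an SVM) under
    leave-one-super-trial-out cross-validation. A seeded generator of
    synthetic two-tool training videos with ground-truth trajectories
    makes every stage testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
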