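Package: sleepaug
Title: Two-Layer Data Augmentation for Sleep-Scoring-Free Insomnia
    Detection from Single-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building insomnia-vs-healthy classifiers from a single
    EEG channel without sleep-stage scoring. Provides a band-structured
    synthetic EEG cohort generator with EDF input/output, wavelet denoising and
    zero-phase Butterworth filtering, five-band discrete wavelet (db8)
    decomposition, signal-level augmentation by per-band-segment scaling and
    noise injection with an additional convolution set, band-wise entropy,
    spectral-power and moment features, a conditional tabular GAN with
    mode-specific normalization for feature-level augmentation, sleep
    architecture summaries (time in bed, sleep latency, total sleep time) from
    clock times, and holdout / k-fold / subject-wise evaluation of five tree
    ensemble classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    pROC,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
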