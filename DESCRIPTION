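Package: hrcascreen
Title: Simulation and Analysis of High-Resolution Cervical Auscultation
    Swallow Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying whether high-resolution cervical
    auscultation (HRCA) recordings of thin-liquid barium swallows and
    water swallows carry systematically different signal features.
    Provides a seeded synthetic-cohort generator for four-channel swallow
    recordings (contact microphone plus tri-axial accelerometer) and for
    feature tables with known participant and material effects; a signal
    conditioning chain (anti-aliased downsampling, autoregressive noise
    whitening, least-squares spline detrending, discrete Meyer wavelet
    denoising); extraction of nine features per channel across the time,
    frequency, time-frequency and information-theoretic domains; a
    per-feature linear mixed-model screen with a participant random
    intercept; and a repeated 70/30 holdout evaluation of linear SVM,
    Gaussian naive Bayes and 2-means classifiers with five confusion
    based performance measures, with or without PCA reduction to eight
    components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    splines,
    signal,
    lme4,
    e1071,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
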