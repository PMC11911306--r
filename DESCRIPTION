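Package: eegage
Title: Peak Alpha Frequency Estimation and EEG-Based Age Prediction from
    Resting-State Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating the peak alpha frequency (PAF) of
    resting-state EEG and for predicting chronological age from the broad
    0.1-45 Hz amplitude spectrum. Implements DC-EEG artifact screening
    against a Savitzky-Golay baseline, autoregressive (covariance method)
    and Welch spectral estimation on a log2-amplitude scale, five PAF
    estimators (naive per-channel peak, SVD-summary peak, a parametric
    aperiodic-plus-Gaussian spectral model, an SNR-weighted channel
    average, and an individually-bounded centre of gravity), partial least
    squares age models with permutation-based factor selection, recursive
    weighted PLS, PARAFAC diagnostics and trilinear PLS on the
    participant-by-channel-by-frequency tensor, and a method-agreement
    statistics layer (Bland-Altman, dependent-correlation tests, MINQUE
    variance components, JZS Bayes factors). A synthetic cohort generator
    produces demographics, ground-truth spectral parameters and raw EEG
    with planted drifts and artifacts so the whole pipeline can be
    exercised without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    signal,
    jsonlite,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
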