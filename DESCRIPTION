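Package: ppgrr
Title: Respiratory Rate Estimation from Photoplethysmogram Signals with a
    Dilated Residual Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for continuous respiratory rate (RR)
    estimation from photoplethysmogram (PPG) waveforms. Provides readers for
    bedside-monitor style recordings (high-rate PPG with a 1 Hz reference RR
    series, breath-annotated capnography benchmarks, and exhalation-marked
    bedside collections), an FIR band-pass / windowing / resampling /
    normalisation preprocessing chain, a respiratory-modulated synthetic PPG
    generator with SNR-calibrated artifact injection, a dilated residual 1-D
    convolutional network regressor trained with subject-wise k-fold
    cross-validation, simplified reference baselines behind a common
    estimator interface, and breathing-group-stratified evaluation with
    Bland-Altman agreement statistics and SNR robustness tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
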