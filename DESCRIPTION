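Package: sanclock
Title: Beat-Interval Variability Analysis and Spectral Signature Filters
    for Sinoatrial Node Function
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of beat-interval (RR) time series from ECG-derived
    tachograms: artifact removal (range, moving-average and quotient
    filters), time-domain and Poincare variability metrics, Welch and
    Lomb-Scargle spectral band powers (VLF/LF/HF), multiscale sample
    entropy, and FIR band-stop "signature" filters that emulate
    anesthesia and autonomic-blockade states from basal recordings.
    Includes a calibrated synthetic RR-cohort generator reproducing
    state-dependent mean beat intervals, spectral band structure, the
    autonomic-blockade broadband power collapse, and the age-linear
    intrinsic heart-rate law, plus MSE-based similarity scoring and
    age-regression validation tools.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
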