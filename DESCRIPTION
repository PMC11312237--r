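Package: eegselect
Title: EEG Channel Selection for Mild Cognitive Impairment Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects mild cognitive impairment (MCI) from multi-channel
    resting-state EEG and searches for minimal electrode subsets that
    preserve detection accuracy. Recordings are band-pass filtered,
    cut into fixed-length segments, and decomposed per channel with a
    level-4 db4 discrete wavelet transform into five reconstructed
    sub-band signals; a non-linear measure (energy, log band power, or
    one of five entropy variants) summarises each sub-band plus the
    original signal into a 6-per-channel feature vector. Classifiers
    (KNN, SVM, discriminant analysis, random forest) are evaluated
    under stratified 10-fold cross-validation, and channels are
    selected by greedy back-elimination / forward-addition or by
    multi-objective optimisation (NSGA-II, NSGA-III, multi-objective
    PSO) trading classification accuracy against electrode count while
    tuning one classifier hyperparameter. A synthetic-cohort generator
    with class-dependent band-power effects on configurable channels
    makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    e1071,
    ranger,
    signal,
    stats,
    utils
Suggests:
    class,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
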