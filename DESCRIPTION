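Package: hearease
Title: Auditory Filter Chains and Predictive Models for Auditory
    Hypersensitivity Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying and supporting auditory hypersensitivity.
    Implements the parametric audio filter chains of a two-task
    psychophysics protocol (a Recollection task, in which listeners
    reproduce how a sound subjectively sounded to them, and an Easing task,
    in which they modify it to be tolerable), including equalizers,
    Butterworth band filters, reverb, flanger, tinnitus and noise
    injection, time-preserving pitch shifting, and a dynamic
    change-suppression gate. Provides a log-mel audio embedding frontend,
    a bidirectional LSTM multi-output regressor (trained with Adam on mean
    squared error) that predicts a listener's filter settings and
    subjective stress ratings from the stimulus and listener covariates,
    the associated evaluation statistics (per-parameter Pearson and
    per-rating Spearman correlations, mean absolute error on native
    scales, filter-usage counts, a test-retest reproducibility index,
    task-contrast tests), and a synthetic experiment generator with a
    known ground-truth response model for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
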