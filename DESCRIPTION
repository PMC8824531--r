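Package: eegdecode
Title: Single-Trial Decoding of Cognitive States from Epoched EEG/MEG
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A complete single-trial decoding pipeline for epoched
    electrophysiological recordings (EEG/MEG). Epochs are transformed to
    normalized band-limited Morlet power (theta/alpha/beta/gamma), from
    which eight feature families are extracted per time window: mean,
    variance, Shannon entropy, phase concentration, inter-regional
    correlation, phase synchrony, autoregressive coefficients, and common
    spatial pattern variances. Features are selected by Fisher-score
    filtering combined with sequential forward selection, class imbalance
    is handled by SMOTE oversampling, and four linear classifiers (naive
    Bayes with full covariances, LASSO, logistic regression, linear SVM)
    are provided together with two multiclass generalization schemes
    (one-vs-rest score voting and an optimal-partition binary decision
    tree). Evaluation uses stratified cross-validation, balanced accuracy,
    and empirical permutation chance levels. A seeded synthetic-data
    generator with known ground truth makes every stage testable without
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
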