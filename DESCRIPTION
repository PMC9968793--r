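Package: riembci
Title: Trial-Wise Riemannian Performance Metrics for Sensorimotor-Rhythm BCI Training
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Riemannian geometry-based user-performance metrics for two-class
    sensorimotor-rhythm brain-computer interface (BCI) training. Implements the
    classDistinct (inter- to intra-class dispersion ratio) and classStability
    (inverse intra-class dispersion) metrics on the manifold of symmetric
    positive-definite trial covariance matrices, together with three trial-wise
    update engines (running, sliding-window and weighted-average) that emit a
    reinforcement signal after every trial, a CSP + regularized-LDA classifier
    baseline with sub-band selection, a synthetic SMR-EEG session simulator,
    EEG preprocessing with Riemannian potato-field artifact rejection, and an
    evaluation battery (Spearman and repeated-measures correlation, bootstrap
    confidence intervals, ROC/AUC with DeLong's test, exact McNemar tests,
    Holm adjustment) that measures how faithfully trial-wise reinforcement
    sums track block-wise performance changes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    pROC,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
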