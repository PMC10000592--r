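Package: ctgkit
Title: Stage-Aware Cardiotocograph Feature Extraction, Classification and
    Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing intrapartum cardiotocograph (CTG) recordings:
    a synthetic CTG generator with ground-truth event logs, iterative fetal
    heart rate baseline estimation, segment-based variability, acceleration
    detection, fuzzy-logic deceleration detection with contraction-relative
    typing (early/late/variable), sinusoidal-pattern screening, an 11-feature
    summary per record, a stratified k-fold cross-validation harness over four
    standard classifiers (random forest, SVM, multilayer perceptron, bagged
    trees) with optional SMOTE balancing of training folds, and an evaluation
    battery (multiclass confusion-matrix metrics, combined performance
    measures, contingency chi-squared, Bland-Altman limits of agreement,
    KMO/Bartlett adequacy diagnostics, one-vs-rest AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    zoo,
    jsonlite,
    nnet,
    rpart,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    caret
Config/testthat/edition: 3
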