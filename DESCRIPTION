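Package: osteovote
Title: Osteosarcoma Histopathology Classification with a Compact CNN and an
    Adapted Majority-Voting Ensemble
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A desk-scale-testable pipeline for three-class osteosarcoma
    histopathology image classification: balanced image-dataset preparation
    (80/20 splitting, oversampling of minority classes to the majority count
    by horizontal flipping, on-the-fly augmentation), a compact convolutional
    neural network expressed as a verifiable architecture specification with
    closed-form shape and parameter accounting plus a pure-R training engine,
    a full evaluation-metric suite (accuracy, precision, recall, F1, Cohen's
    kappa, multiclass log-loss, one-vs-rest ROC-AUC, confusion matrices), and
    an adapted majority-voting ensemble with probability tie-breaking and
    brute-force search over all base-learner subsets of size two or more.
    Includes a synthetic-data module generating class-separable RGB images and
    base-learner probability matrices with controllable accuracy, so every
    stage is testable without the external dataset.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    e1071,
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
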