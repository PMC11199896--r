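Package: errpnet
Title: Cross-Task Classification of Error-Related Potentials with a
    Convolution-Transformer Network and Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying error-related potentials (ErrPs) in
    two-channel EEG epochs. Implements a dual-branch neural network that
    extracts electrode-sequence and time-sequence features with
    convolutional front-ends and transformer encoder layers, trained with
    a pretrain/fine-tune transfer-learning strategy, leakage-safe
    SVM-guided minority oversampling (SVMSMOTE) inside stratified K-fold
    cross-validation, and the standard cross-subject evaluation protocols
    (within-session, cross-session, leave-one-subject-out,
    one-train-one-test, cross-task). Includes a canonical preprocessing
    pipeline (Butterworth bandpass, epoch extraction, downsampling,
    channel selection, amplitude scaling), an HDF5 epoch store, and a
    synthetic ErrP generator with per-subject variability and cross-task
    distribution shift so the full pipeline is testable without EEG
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    generics,
    ggplot2,
    e1071,
    signal,
    MASS,
    rhdf5,
    yaml,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    purrr,
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
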