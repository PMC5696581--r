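Package: icdcnn
Title: Chapter-Level ICD-10-CM Coding of Discharge Notes with a
    Multi-Channel Text CNN
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assigns chapter-level ICD-10-CM diagnosis codes to free-text
    hospital discharge notes. Encodes each note as a matrix of pretrained
    word embeddings and classifies it with a single-layer convolutional
    neural network using five filter-height channels (1-5 word regions),
    max pooling, dropout and a logistic output, trained by minibatch
    gradient descent with momentum, L2 regularisation and early stopping.
    Also provides the classical bag-of-words baselines (support vector
    machines with four kernels, random forest, gradient boosting), the
    one-vs-rest evaluation protocol (oversampling, 5-fold cross-validation,
    date-based train/test splits, ROC AUC and F-measure with global and
    lowest-5 summaries), a filter-level information-gain interpretability
    analysis, and a synthetic discharge-note corpus generator with
    concept-clustered embeddings for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    e1071,
    randomForest,
    xgboost,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
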