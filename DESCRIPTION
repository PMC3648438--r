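Package: smotehd
Title: SMOTE and Class-Imbalance Corrections for High-Dimensional Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying class-imbalance corrections on
    high-dimensional (p >> n) two-class data. Implements the SMOTE synthetic
    minority oversampling generator with full provenance, simple undersampling
    and classification-threshold (cut-off) adjustment; block-exchangeable
    Gaussian and exponential data generators emulating gene-expression-like
    designs; pooled-variance t-statistic variable selection; a suite of eleven
    classifiers (k-NN, diagonal linear and quadratic discriminant analysis,
    nearest shrunken centroids, CART, random forest, SVM, and L1/L2 penalized
    logistic regression) behind a single posterior-score interface; evaluation
    by class-specific accuracy, AUC and G-mean with independent-test-set and
    repeated leave-one-out cross-validation protocols; and Monte-Carlo checks
    of the theoretical moment, correlation and nearest-neighbor distance
    properties of SMOTE in high dimensions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    rpart,
    randomForest,
    e1071,
    glmnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
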