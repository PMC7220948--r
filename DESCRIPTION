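Package: vifsig
Title: Minimal Low-Collinearity Gene-Expression Signatures via SVM-RFE and
    Variance-Inflation-Factor Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds compact gene-expression signatures for binary outcome
    prediction (e.g. 5-year distant metastasis) by combining a Student's
    t-test intensity screen, linear-kernel support-vector-machine recursive
    feature elimination (SVM-RFE), variance-inflation-factor (VIF)
    constrained forward selection to remove multicollinearity, and a
    cross-validated differential-AUC rule for choosing the operating gene
    count. Includes multiple-logistic-regression, linear-SVM and
    random-forest predictors, repeated stratified-split internal and
    external validation with Mann-Whitney comparisons, per-dataset Z-score
    renormalisation for cross-study transfer, and a synthetic expression
    data generator so the whole pipeline is testable without microarray
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    glmnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
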