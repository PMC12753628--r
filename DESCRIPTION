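Package: crossrad
Title: Cross-Species Reproducibility Screening and Transfer of MRI Radiomics Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for assessing whether MRI radiomics features of the
    intervertebral disc are reproducible between humans and experimental
    monkeys, and for transferring disc-degeneration classifiers across
    species. Implements the canonical radiomics feature taxonomy, a
    synthetic cohort generator with planted species shifts, degeneration
    effects and observer noise, a compact IBSI-style 2D feature extractor,
    a two-step interspecies reproducibility screen (independent-samples
    t-test followed by an inverted species LASSO), per-feature intra- and
    interobserver ICC(2,1) filtering, mutual-information plus
    cross-validated LASSO dimensionality reduction, SMOTE class balancing,
    and cross-species evaluation of five classifiers with ROC/AUC and
    confusion-based metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    rpart,
    randomForest,
    jsonlite,
    withr,
    rlang,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
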