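Package: tabml
Title: Supervised Machine Learning Pipelines for Tabular Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end supervised machine learning pipeline for tabular
    feature tables such as microbiome OTU relative abundances: reproducible
    preprocessing of mixed continuous/categorical features (one-hot encoding,
    centring and scaling, near-zero-variance filtering, collapsing of
    perfectly correlated features), outcome-stratified or group-aware
    train/test splitting, hyperparameter tuning by repeated k-fold
    cross-validation over per-model default grids, held-out model evaluation
    (AUROC, AUPRC, accuracy and friends), permutation-test feature importance
    with empirical p-values, and a multi-seed workflow that summarises
    performance across many train/test splits.  Models are fitted through
    glmnet, e1071, rpart, randomForest and xgboost.  A command-line entry
    point exposes the pipeline to shell users.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    e1071,
    rpart,
    randomForest,
    xgboost,
    jsonlite,
    yaml,
    optparse,
    parallel,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    caret,
    withr
Config/testthat/edition: 3
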