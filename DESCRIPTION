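Package: scIFS
Title: Cell-State Classification for Single-Cell RNA-Seq by Ranked
    Incremental Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks genes of a labelled single-cell expression matrix by
    three importance scores (multiclass F-score, squared coefficient of
    variation above a fitted technical baseline, and PCA-loading
    importance), selects a compact predictive gene subset by incremental
    feature selection over four classifier families (k-nearest
    neighbours, support vector machine, random forest, gradient-boosted
    trees) under stratified cross-validation, and evaluates multiclass
    cell-state predictions with macro metrics, confusion matrices and
    one-vs-rest ROC/AUC. Includes quality-control filters, stratified
    train/test splitting, readers and writers for the 10x Matrix Market
    triplet and dense CSV formats, a negative-binomial synthetic data
    generator with planted marker genes, and an end-to-end pipeline
    runner with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    e1071,
    ranger,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
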