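Package: pgselect
Title: Peculiar Gene Selection for Imbalanced Expression Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A three-step feature-selection workflow for binary classification
    of high-dimensional gene-expression data under class imbalance. Genes are
    first screened by (optionally moderated) differential-expression tests,
    then scored by the in-sample predictive power of single-gene logistic
    regressions, and finally a binary vote matrix over the strongest
    predictors is mined for "peculiar" genes: those that correctly classify
    the samples most often misclassified by the majority of predictors. The
    resulting class-specific signatures can be evaluated with a support-vector
    machine over a parameter grid (kernel, cost, class weights) under
    stratified k-fold cross-validation, optimising overall accuracy or the
    recall of either class. A synthetic-data generator with planted common
    markers, hard samples and peculiar markers makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
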