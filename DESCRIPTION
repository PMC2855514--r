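Package: hetsig
Title: Outcome Classification and Molecular Heterogeneity Analysis for
    Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and fairly evaluating gene-expression and
    clinical classifiers of lethal versus indolent prostate cancer, and for
    quantifying the molecular heterogeneity of outcome classes. Implements a
    split-sample protocol with iterated stratified 10-fold cross-validation
    and strictly in-fold feature selection (threshold and stepwise), diagonal
    linear discriminant analysis, k-nearest-neighbour, nearest-template and
    ridge-penalised logistic scorers, Mann-Whitney AUC with bootstrap and
    cross-validation confidence intervals, silhouette-width homogeneity
    scores with structure categories, stroma-contamination flagging,
    categorical association statistics (Cramer's V, Fisher's exact test,
    odds ratios), a GEO series-matrix importer, and a seeded synthetic-cohort
    generator that reproduces the statistical structure these analyses
    assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    cluster,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
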