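Package: mscpotency
Title: Consensus Metabolite Modeling of Mesenchymal Stromal Cell Potency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A consensus machine-learning framework for discovering metabolite
    panels predictive of mesenchymal stromal cell (MSC) immunomodulatory
    potency. Provides feature-table preprocessing for untargeted MS and NMR
    metabolomics (blank/QC filtering, relative-SD filtering, median
    normalization, autoscaling, empirical-Bayes batch correction, timepoint
    differencing, variance filtering guided by partial least squares), a
    composite potency score from functional assay panels via principal
    component analysis, a seven-family regression suite (PLSR, linear SVR,
    random forest, gradient boosting, decision tree, LASSO, and genetic
    programming symbolic regression) with grid-search cross-validation,
    same-family feature selection, normalized variable importances and
    leave-one-out R2, cross-model consensus panel construction with consensus
    refitting and outlier-line ablation, hypergeometric pathway
    over-representation analysis, and a seeded synthetic-study generator with
    planted signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    randomForest,
    rpart,
    xgboost,
    e1071,
    mixOmics,
    sva,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
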