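Package: profwise
Title: Hybrid LASSO/mRMR Feature Selection with Rank-Based Weighting for
    Proteomic Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the ProFWise ensemble feature-selection workflow for
    high-dimensional proteomic expression matrices. Inside stratified
    cross-validation folds, features are selected both by a from-scratch greedy
    minimum-redundancy maximum-relevance (mRMR) ranking and by L1-penalized
    (LASSO) model fits; per-fold selections are aggregated into integer
    feature weights under rank-based method weights, a minimum-weight
    threshold is swept to produce nested candidate subsets, and the subset
    maximizing cross-validated predictive performance with the fewest
    features is chosen. Supports binary classification (e.g. MGMT promoter
    methylation status) and continuous regression (e.g. MGMT protein
    expression) targets, ships a synthetic proteomics generator with planted
    ground truth, class-mean alteration analysis, run comparison utilities,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    e1071,
    randomForest,
    rpart,
    class,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
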