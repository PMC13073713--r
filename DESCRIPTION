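Package: riskstack
Title: Bagging-Stacking Ensembles with Hybrid Resampling for Imbalanced Risk Prediction
Version: 0.1.0
Authors@R:
    person("riskstack", "developers", email = "riskstack@example.org", role = c("aut", "cre"))
Description: Multi-class risk prediction for food-safety inspection records under
    severe class imbalance. Implements a unified bagging-stacking framework:
    stratified bootstrap subsets balanced by SMOTE-Tomek hybrid resampling,
    heterogeneous stacking ensembles of gradient-boosted and random-forest tree
    learners fused out-of-fold by a multinomial logistic meta-learner, soft-voting
    aggregation across bags, and an independent probability threshold for the
    high-risk class. Ships a synthetic inspection-record generator with the
    field schema and imbalance structure of national sampling programmes, a
    feature-engineering pipeline (cyclical month encoding, shelf-life binning,
    one-hot encoding, zero-variance filtering), evaluation metrics (per-class
    precision/recall/F1, macro- and weighted-F1, one-vs-rest AUC), threshold
    sweep utilities, and experiment harnesses for benchmark and robustness
    studies, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
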