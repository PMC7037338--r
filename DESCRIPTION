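Package: flowps
Title: Floating Window Projective Separator for Omics-Based Response
    Classification
Version: 0.1.0
Authors@R:
    person("flowps", "maintainers", email = "maintainers@flowps.dev",
           role = c("aut", "cre"))
Description: Sample-specific flexible data trimming for binary treatment-response
    classification from gene-expression profiles. For every query sample the
    floating window projective separator (FloWPS) removes features on which the
    query would require extrapolation and restricts training to its nearest
    neighbours, then averages base-learner predictions over a set of trimming
    parameters selected by nested leave-one-out cross-validation. Ships seven
    pluggable base learners (linear SVM, kNN, random forest, ridge regression,
    Bernoulli naive Bayes, AdaBoost, multi-layer perceptron), AUC-ranked core
    marker-gene selection, cost-balanced decision thresholds, per-method feature
    importance extraction with cross-method correlation analysis, and a synthetic
    data generator emulating clinical transcriptomic cohort geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
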