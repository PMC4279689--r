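Package: synforest
Title: Synthetic Random Forests with Nodesize-Grid Synthetic Features
Version: 0.1.0
Authors@R: person("synforest", "maintainers", email = "maintainers@synforest.org", role = c("aut", "cre"))
Description: Builds synthetic random forests: a portfolio of random forests is
    grown over a grid of terminal nodesize values, each forest contributes its
    out-of-bag predictions as synthetic features, and a secondary hyperforest is
    fitted on the original features augmented with the synthetic ones. Includes
    a self-contained random forest engine (bagged CART with mtry feature
    subsampling and explicit in-bag bookkeeping), the COBRA locally weighted
    zero-one aggregation method for regression collectives, seeded generators
    for the Friedman regression surfaces and the twonorm/threenorm/ringnorm
    Gaussian classification mixtures, standardized mean squared error and
    normalized Brier score metrics, a replication benchmark harness, exact
    Wilcoxon signed-rank and Iman-Davenport modified Friedman rank tests, and a
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
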