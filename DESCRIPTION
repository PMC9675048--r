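Package: nradjust
Title: Nonresponse-Adjusted Estimation of Patient-Reported Opioid
    Consumption Quantiles
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating post-discharge opioid consumption quantiles
    from SMS-to-web survey data linked to electronic health record covariates,
    under informative survey nonresponse. Implements synthetic cohort
    simulation, generalized low-rank model imputation with missingness
    indicators, bivariate nonresponse diagnostics, cross-validated stacked
    ensembles (Super Learner), targeted double-robust estimation of
    consumption distribution functions and quantiles with influence-curve
    confidence intervals, tree-split variable importance, and guideline-style
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    glmnet,
    quadprog,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
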