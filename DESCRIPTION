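Package: effsim
Title: Monte-Carlo Evaluation of Technical-Efficiency Estimators for
    Health Facilities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A simulation laboratory for benchmarking technical-efficiency
    estimators on multi-output health-facility production data typical of
    low-resource settings. Generates facility panels with known true
    efficiency under linear, fixed-input, Cobb-Douglas and piecewise
    Cobb-Douglas technologies with configurable efficiency distributions and
    measurement error; estimates efficiency by output-oriented constant
    returns to scale data envelopment analysis (DEA) with super-efficiency
    outlier filtering, percentile-restricted DEA with data-driven
    assurance-region weight bounds, a restricted Cobb-Douglas stochastic
    output distance function with normal/half-normal composed error and JLMS
    conditional efficiencies, and an ensemble of the two restricted
    estimators; and summarises accuracy by five criteria (median absolute
    deviation, misclassification at the frontier, under- and over-estimation
    rates, Spearman rank correlation) averaged over replications.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
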