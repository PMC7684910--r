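Package: qrfcost
Title: Quantile Regression Forest Analysis of High Healthcare Episode Costs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and quantifies determinants of high healthcare episode
    costs with quantile regression forests. Provides a calibrated synthetic
    generator for skewed, heteroscedastic oncology episode expenditures with
    known conditional quantiles; quantile regression forests with
    out-of-bag conditional quantile prediction and permutation variable
    importance; backward stepwise variable selection by out-of-bag average
    quantile loss with relative-importance decomposition; and linear quantile
    regression with natural cubic spline terms and bootstrap confidence
    intervals to quantify quantile-varying covariate effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ranger,
    Rcpp,
    splines,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
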