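Package: nlmetrt
Title: Treatment-Effect Testing with Nonlinear Mixed-Effects Models
Version: 0.1.0
Authors@R: person("Pharmacometrics", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Framework for assessing treatment effects in balanced two-arm
    longitudinal trials with nonlinear mixed-effects models. Implements seven
    testing approaches (standard AIC selection with the likelihood ratio test,
    structural-similarity selection, combined and randomized combined LRT with
    empirical null distributions, Akaike-weight model averaging across drug
    models and across placebo-and-drug model grids, and individual model
    averaging via subject-level mixture models), together with a synthetic
    natural-history cohort generator emulating ADAS-cog-like disease
    progression and an evaluation battery for type I error, power, and RMSE
    of treatment-effect estimates. Marginal likelihoods are computed in closed
    form for linear-Gaussian models and by Laplace approximation otherwise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
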