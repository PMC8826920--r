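Package: wbcausal
Title: Causal Machine Learning for Effects of Student Well-Being on
    Academic Achievement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the average treatment effect of adolescent
    subjective well-being (anxiety, depression and positive-affect
    subscales, or their first-principal-component composite index) on
    later standardized test scores from observational student cohorts
    with many mixed-type, partially missing controls.  Provides five
    response-surface estimators sharing a common prediction contract --
    Bayesian ridge regression with type-II maximum-likelihood
    hyperparameters, its Nystroem-kernelized variant, a two-stage
    kernelized ridge with an unregularized treatment coefficient,
    stagewise least-squares gradient boosting, and double machine
    learning with cross-fitting -- together with plugin
    partial-dependence curves for E[Y|do(T=t)], bootstrap-reimputation
    uncertainty bands, standardized effect sizes with conservative
    finite-sample t-tests, school-stratified cross-validation for
    hyperparameter selection, and a synthetic school-cohort generator
    with known ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
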