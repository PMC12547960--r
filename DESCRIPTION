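Package: volhealth
Title: Income Volatility and Health: Concavity Decomposition and
    Counterfactual Analysis for Monthly Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the association between month-to-month
    income volatility and health in longitudinal panel data.  Provides
    person-level volatility statistics (simple and time-adjusted standard
    deviations), general linear models of averaged health outcomes on
    income level and volatility with variance-explained decomposition,
    penalized-spline (GAM) estimation of the income-health dose-response
    with derivative-based concavity checks, a decomposition separating
    Jensen-type concavity effects from direct volatility effects,
    multilevel triangulation with participant random intercepts, a
    zero-volatility counterfactual summarised as Hedges' g and
    clinical-cutoff prevalence, and a synthetic panel generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    mgcv,
    car,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
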