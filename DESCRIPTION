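Package: nmasurv
Title: Bayesian Parametric Survival Network Meta-Analysis from Digitized
    Kaplan-Meier Curves
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Indirect comparison of overall survival between treatments that
    share a common comparator arm but were never compared head to head.
    Reconstructs pseudo individual-patient data from digitized Kaplan-Meier
    coordinates and numbers-at-risk tables (the Guyot algorithm), bins them
    into monthly interval counts, and fits Bayesian parametric survival
    network meta-analysis models under exponential, Weibull, Gompertz and
    log-logistic families, yielding time-varying hazard ratios, adjusted
    survival curves, probability-of-best-treatment series and DIC model
    ranking.  Also implements the classical Bucher indirect comparison from
    reported summary hazard ratios.  Includes a synthetic-trial generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
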