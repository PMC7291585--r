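Package: agreemix
Title: Agreement Analysis for Clustered Repeated-Measures Method
    Comparison Studies
Version: 0.1.0
Authors@R:
    person("agreemix", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies agreement between two measurement devices from
    clustered, unbalanced, time-matched repeated-measures data.  Implements
    five agreement indices -- the repeated-measures concordance correlation
    coefficient, mixed-effects limits of agreement, coverage probability,
    total deviation index, and coefficient of individual agreement -- as
    functions of variance components estimated by REML from crossed
    random-intercept linear mixed models.  Includes subject-level (cluster)
    bootstrap confidence intervals, a nonparametric total deviation index,
    model diagnostics, Bland-Altman plot specifications, a synthetic-data
    generator for unbalanced designs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
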