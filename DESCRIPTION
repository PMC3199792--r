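Package: smokerisk
Title: Prognostic Scoring of Adolescent Daily-Smoking Initiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and internal validation of a Framingham-style
    prognostic tool for the one- and two-year risk that an adolescent
    initiates daily cigarette smoking. Provides a seeded synthetic
    longitudinal cohort generator (quarterly questionnaire cycles,
    smoking-recall items, household and peer smoking covariates,
    education-dependent item missingness), construction of pooled
    discrete-time wave risk sets, multiple imputation by chained
    equations, multivariable logistic model fitting with Rubin pooling,
    bootstrap calibration-slope shrinkage correction, calibration and
    discrimination statistics (Hosmer-Lemeshow, c-statistic,
    maximum-rescaled R-squared, discriminating-informativeness ratio),
    and conversion of logistic coefficients into integer points tables
    with a points-to-risk lookup, including the published equations and
    tables as fixtures with worked-example scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    nnet
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
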