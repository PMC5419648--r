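Package: gentapk
Title: Population Pharmacokinetics of Gentamicin with Iterative Two-Stage
    Bayesian Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-compartment intravenous-infusion pharmacokinetic model for
    gentamicin with covariate submodels (Cockcroft-Gault creatinine clearance,
    corrected lean body mass), maximum a posteriori (MAP) Bayesian estimation
    of individual parameters, Iterative Two-Stage Bayesian (ITSB) population
    fitting with per-parameter Bayesian/FPB/Fixed settings, external model
    validation via median (absolute) prediction errors with bootstrap
    confidence intervals, Monte-Carlo and Bayesian forecasting of
    concentration-time profiles, and dose recommendation for once-daily
    peak/trough targets. Includes a synthetic-cohort generator emulating the
    demographic and sampling structure of adult endocarditis treatment
    courses, so the whole pipeline runs end-to-end without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
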