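Package: ckdsim
Title: Microsimulation of the Lifetime Risk of Chronic Kidney Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An individual-level, annual-cycle microsimulation of chronic
    kidney disease (CKD). Each simulated person carries an eGFR trajectory
    driven by a mixed-effect slope model (covariate effects for sex, race,
    proteinuria, diabetes, hypertension and obesity, with a person-level
    random slope), KDIGO staging with sequential stage bookkeeping,
    obesity-mediated incidence of diabetes, hypertension and cardiovascular
    disease, annual BMI drift, and all-cause mortality with stage- and
    CVD-specific hazard multipliers. The package estimates the lifetime
    risk of CKD (any stage, and highest stage attained) by baseline BMI
    category with percentile-bootstrap confidence intervals and one-way
    sensitivity analyses, and ships a synthetic US-adult-like cohort
    generator so the full pipeline runs without restricted survey data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
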