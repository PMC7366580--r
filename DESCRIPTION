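Package: biaval
Title: Validation of Drug Budget-Impact Models Against Realised Utilisation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recreates gross drug budget-impact models (eligible population,
    market share, dosage and acquisition cost over a five-year horizon) as a
    canonical multiplicative cohort engine, propagates parameter uncertainty
    through a Monte-Carlo probabilistic sensitivity analysis (uniform +/-20
    percent by default, list price held fixed), aggregates monthly dispensing
    ledgers into annual realised utilisation at list price from the month of
    reimbursement, and compares predicted with realised spending: signed
    prediction-error percentages, over/under-prediction classification, and
    coverage of realised utilisation by the simulated bounds. Includes the
    health-technology-assessment selection rules and parameter/feature
    censuses used in national reimbursement audits, reference tables from an
    Irish audit of twelve reimbursed drugs, and a synthetic-data generator
    (applicant-style model specifications, forecast-error-perturbed
    dispensing ledgers, HTA registries) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
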