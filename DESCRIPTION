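Package: benzrisk
Title: Occupational Benzene Inhalation Risk Assessment and Biomarker Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chronic inhalation risk assessment for workers occupationally
    exposed to benzene. Computes body-weight-dependent breathing rates,
    ppm to mg/m3 conversion, chronic daily intake and the non-carcinogenic
    Risk Quotient (intake over reference dose) for a worker roster, classifies
    workers against the 0.5 ppm threshold limit value and the RQ >= 1 rule,
    builds descriptive frequency and summary tables, and screens exposure
    metrics against oxidative-stress (malondialdehyde) and kidney-function
    (blood urea nitrogen, creatinine) biomarkers with Pearson correlations
    and t-based two-sided p-values. A synthetic cohort generator with
    configurable exposure-biomarker links supports power and type-I-error
    characterisation of small-cohort correlation screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
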