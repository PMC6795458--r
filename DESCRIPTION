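Package: nbarti
Title: Claims-Based Measurement of Antibiotic Prescribing for Non-Bacterial
    Acute Respiratory Tract Infections
Version: 0.1.0
Authors@R: person("nbarti", "developers", email = "dev@example.org",
    role = c("aut", "cre"))
Description: Builds outpatient consultation cohorts for non-bacterial acute
    respiratory tract infections (NB-ARTI) from administrative claims tables,
    classifies diagnosis-level antibiotic appropriateness, links same-date
    systemic antibiotic (ATC J01) prescriptions, and computes monthly
    prescribing rates, linear trends, and crude and adjusted odds ratios from
    logistic regression. Includes a synthetic claims generator with known
    ground truth so every pipeline stage is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
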