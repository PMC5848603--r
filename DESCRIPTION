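Package: cmcr
Title: Complexity-Based Model for Categorizing Rehabilitation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a complexity-based model for categorizing
    rehabilitation patients: configurable severity-scoring matrices that map
    standardized clinical assessments (MRC-Sum Score, FSS-ICU, handgrip
    dynamometry, S5Q, ventilatory parameters) to three severity levels and a
    low/medium/high complexity category with an associated therapeutic load.
    Also provides the quarterly adherence quality indicator built from
    inpatient care-instance logs, Prais-Winsten regression (linear trend with
    first-order autoregressive errors) for adherence time series including a
    between-group trend comparison, and a seeded synthetic patient-record
    generator so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
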