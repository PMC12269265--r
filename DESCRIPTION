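Package: sepsisclaims
Title: Claims-Based Sepsis and Septic Shock Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for claims-based surveillance of sepsis and septic shock
    in administrative inpatient databases of the Japanese DPC type. Provides
    a seeded synthetic claims generator, an operational phenotyping algorithm
    (presumed serious infection from blood cultures plus qualifying
    intravenous antibiotic courses, acute organ dysfunction from treatment
    procedures and ICD-10 codes, vasopressor-defined septic shock,
    community onset within 48 hours), patient-level deduplication, and the
    descriptive, trend (Cochran-Armitage, linear regression) and adjusted
    mortality (iteratively reweighted least squares logistic regression)
    statistics used to summarise such cohorts, together with a reporting
    pipeline that assembles characteristics tables, outcome tables and
    yearly trend tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
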