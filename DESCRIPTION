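Package: carecascade
Title: Care-Cascade Costing and Screening Optimization for Type 2 Diabetes Programmes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the type 2 diabetes care continuum in a
    health region: a deterministic compartmental model of patient flow with
    coverage-driven transition rates, a bottom-up unit-costing and spending
    ledger, saturating cost-coverage curves for outreach screening, a grid
    optimizer for the facility/outreach screening mix that minimizes the cost
    per newly identified case, and the investment arithmetic linking glucose
    control to co-payment offsets, monitoring-cost savings, and adherence
    counselling scale-up. Includes a synthetic-region generator with known
    parameters so every stage is testable without access to patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
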