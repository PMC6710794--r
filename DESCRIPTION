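Package: preecon
Title: Health-Economic Evaluation of sFlt-1/PlGF Rule-Out Testing in Suspected Preeclampsia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort decision-tree cost model comparing standard of care with
    and without sFlt-1/PlGF ratio testing for pregnant women with suspected
    preeclampsia, from a Swiss healthcare-system perspective. Implements the
    strategy comparison on branch-level cohort counts and per-patient costs,
    a five-year budget-impact projection under a testing-uptake schedule with
    discounting, one-way deterministic sensitivity analyses and named
    scenarios (retesting, exclusion of birth costs), an itemised outpatient
    tariff/inpatient DRG costing layer, and a patient-level microsimulation
    that cross-checks the deterministic expectations and emulates an
    inpatient cost registry. All model parameters live in a single
    configuration document with per-field provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
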