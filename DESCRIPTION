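Package: pecost
Title: Decision-Analytic Cost Model for sFlt-1/PlGF-Based Preeclampsia Triage
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Evaluates the economic impact of adding the sFlt-1/PlGF ratio
    test (cutoff 38) to standard surveillance of women with suspected
    preeclampsia, from a Japanese healthcare-payer perspective. Implements
    the two-scenario (no-test vs test) decision tree analytically: expected
    per-patient and whole-cohort costs, per-patient saving and budget
    impact, closed-form calibration of the neonatal intensive care length
    of stay, one-way sensitivity scenarios with tornado ranking, and a
    patient-level synthetic cohort generator for Monte Carlo validation of
    the analytic expectations. Parameters are supplied via a JSON
    configuration file; results serialize to CSV and JSON with run
    manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
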