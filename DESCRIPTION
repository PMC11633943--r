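Package: icurounds
Title: Rule-Based Clinical Decision Support for Daily ICU Quality Metrics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A dynamic, rule-based clinical decision support engine for the
    standard quality metrics reviewed daily on adult intensive care unit
    patients.  Evaluates 23 metrics across seven categories (hypoglycemia,
    venothromboembolism prophylaxis, stress ulcer prophylaxis, mechanical
    ventilation, sedation, nutrition, and catheter removal/risk) against a
    typed electronic-health-record event stream, producing binary actionable
    flags with auditable reason codes.  Implements explicit missing-data
    semantics (expected-present, expected-absent, assume-normal-lab), a
    medication source-of-truth hierarchy (orders and MAR actions over note
    documentation), a seeded synthetic patient-day generator with per-metric
    ground truth, and confusion-matrix validation including exact integer
    reconstruction of confusion counts from rounded published statistic rows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
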