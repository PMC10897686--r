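Package: rxpathways
Title: Treatment Pathways and Resistance Status from Antidepressant
    Prescription Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives depression care pathways from raw primary-care
    prescription and coded-event records. Prescriptions are expanded into
    drug coverage intervals, stitched into maximal constant-regimen
    treatment sequences, and classified against rule-based outcome
    definitions (response, remission, relapse, switching, combination,
    augmentation, resumption and treatment failure), yielding a
    per-patient classification of major depressive disorder versus
    treatment-resistant depression with line-of-therapy counts. Includes
    cohort eligibility screening, per-patient and per-group summary
    metrics with small-cell disclosure control, the two inferential tests
    used for group comparison, and a label-first synthetic cohort
    generator that carries ground-truth labels so every classification
    rule can be validated without access to restricted health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
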