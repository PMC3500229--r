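Package: dmphenotype
Title: Claims-Based Case Definition for Incident Diabetes in Children and Youth
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A rule-based phenotyping engine that identifies newly diagnosed
    (incident) diabetes mellitus in administrative healthcare claims for
    persons aged 6-24 years. Implements a configurable ICD-9-CM code-set
    registry, a new-user cohort builder with a 365-day washout and a 90-day
    post-discharge initiation allowance, primary and secondary case-definition
    variants with encounter confirmation logic, a polycystic ovarian syndrome
    exclusion window, index-date reset, and type 1 / type 2 subtype
    classification. Ships validation statistics (positive predictive value
    with Wilson score intervals, design-weighted sensitivity and specificity
    under partial adjudication), contingency reporting, and a seeded synthetic
    claims generator with planted ground truth covering the major
    misclassification scenarios, so the whole pipeline is testable without
    access to real claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
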