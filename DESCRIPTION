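Package: laipersist
Title: Treatment Persistence of Long-Acting Injectable Antipsychotics
    from Pharmacy Dispensing Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds continuous-treatment episodes from longitudinal
    prescription-pickup records using a permissible-gap (days-of-supply plus
    grace period) rule, and compares time to discontinuation of long-acting
    injectable antipsychotics across drug cohorts. Implements pharmacy- and
    patient-level eligibility filtering for panel dispensing databases,
    new-initiator (washout) cohort selection, prior- and post-discontinuation
    treatment classification including restart detection, dose and
    combination-therapy metrics, and Kaplan-Meier, Cox proportional-hazards
    and logistic restart comparisons. Ships a synthetic dispensing-data
    generator with known ground truth so the full pipeline is testable
    without access to proprietary pharmacy panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
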