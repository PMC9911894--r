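Package: noduletriage
Title: Rule Engines and Accuracy Statistics for Thyroid Nodule Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes three thyroid nodule triage algorithms as auditable rule
    engines: ACR TI-RADS additive point scoring with size-dependent biopsy
    thresholds, the AACE/ACE/AME three-tier ultrasound risk classification,
    and the TNAPP integrated clinical-plus-ultrasound decision algorithm.
    Provides diagnostic test accuracy statistics (sensitivity, specificity,
    predictive values, accuracy) against cytologic or histologic reference
    standards, pairwise percent-agreement concordance overall and stratified
    by nodule diameter, avoidable-biopsy and missed-malignancy profiling,
    and a seeded synthetic cohort generator so the full triage pipeline can
    be exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
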