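Package: progrisk
Title: Progressive Risk Formulations for Longitudinal Disease-Progression Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form progressive risk compositions that force predicted
    event risk to be non-decreasing across sequential scans of the same
    subject, together with comparator margin-loss and Siamese contrastive
    regularizers, case-control cohort construction (exact demographic matching
    with a BMI tolerance, horizon labelling, scan-pair selection), nested
    cross-validation with ensembling, and scan-level evaluation (AUROC, AUPRC,
    bootstrap confidence intervals, the DeLong test for paired AUROCs,
    subgroup and per-grade breakdowns). Includes a synthetic longitudinal
    cohort simulator with monotone latent severity, event times, ordinal
    grades and demographics, so the full pipeline runs at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
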