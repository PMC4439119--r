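Package: mircq
Title: Biomarker Screening for CSF miRNA RT-qPCR Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cerebrospinal-fluid microRNA biomarker
    discovery from RT-qPCR quantification-cycle (Cq) panels. Covers
    detection census and frequency-of-occurrence filtering, stability-based
    reference-assay selection, delta-Cq normalization and fold changes, an
    explorative rank-based measure-of-relevance screen with subsampling
    reliability analysis, confirmatory MANCOVA with Wilks' lambda and
    Bonferroni adjustment, linear discriminant classification with ROC/AUC
    evaluation, and a synthetic cohort generator that emulates the
    case/control study design the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
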