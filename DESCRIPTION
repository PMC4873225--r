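Package: prostmark
Title: Prostate Cancer Biomarker Prioritization, qPCR Validation and
    Organoid Morphometry
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-stage analysis pipeline for prostate cancer biomarker
    discovery and validation. Ranks candidate genes from a grouped
    (normal / primary tumor / metastasis) expression matrix by fold change
    and a battery of significance tests, then filters candidates by
    multiple-testing correction, tissue-specific expression, Kaplan-Meier
    survival stratification and literature novelty. Implements spike-in
    standardized absolute qRT-PCR quantification with detection calling,
    Mann-Whitney contrast batteries, clinical dichotomizations and ROC/AUC
    evaluation; siRNA knockdown, viability and wound-healing assay
    quantification; and organoid morphometric image analysis
    (area, roundness, roughness, protrusion counting, live/dead signals).
    Ships synthetic-data generators that emulate the statistical structure
    of such studies, including cancer-adjacent field effects, so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
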