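Package: qpopr
Title: Quadratic Phenotypic Optimization for Ex Vivo Drug Combination Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for combinatorial functional precision medicine
    screens: constructs orthogonal-array composite designs (OACD) for
    multi-drug, three-level dose panels; normalizes 384-well viability
    readouts to untreated controls with Z'-factor and SSMD quality gates;
    fits patient-specific full quadratic response surfaces by ordinary least
    squares; exhaustively ranks all 3^k dose-level combinations by predicted
    normalized cell viability; and evaluates concordance between predicted
    and clinical treatment response (confusion summaries, exact and
    continuity-corrected binomial intervals, Fisher's exact test, ROC/Youden
    analysis, paired comparisons). Includes a synthetic-data generator that
    emulates plates, cohorts and serial resistance drift from known
    ground-truth surfaces so that every pipeline stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
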