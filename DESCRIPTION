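Package: cytogate
Title: Hierarchical CMD Gating and Slide-Level Evaluation for Quantitative Cervical Cytology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for population-scale analysis of AI-classified cervical
    cytology. Each detected cell carries a vector of per-class confidence
    values (CMD markers, independent sigmoid outputs in [0,1]); the package
    assigns cell labels by hierarchical gating, aggregates per-slide class
    counts, scores slides for LSIL+ and HSIL+ endpoints, and runs the full
    evaluation protocol: one-sided Mann-Whitney tests with Cliff's delta
    effect sizes and Benjamini-Hochberg q-values, empirical ROC curves with
    stratified-bootstrap percentile bands, Wilson intervals for human triage
    operating points, matched-specificity/sensitivity comparisons, per-cell
    threshold sweeps, and LOWESS age trends with bootstrap bands. A
    synthetic multi-centre cohort generator with known ground truth and a
    z-stack detection-grouping/focus-selection component for single-cell
    extraction make every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
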