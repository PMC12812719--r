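Package: glycoprog
Title: Longitudinal OGTT Analysis of Progression to Dysglycemia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing 10-year longitudinal oral glucose tolerance
    test (OGTT) cohorts with biannual visits. Implements ADA-based per-visit
    glycemic classification (normal glucose tolerance, prediabetes, diabetes),
    study-eligibility filtering, OGTT surrogate indices of insulin sensitivity
    and beta-cell function (Matsuda, HOMA-IS/IR, HOMA-beta, insulinogenic
    index, oral disposition index), 10-year decline statistics (DIS, DBCF),
    median-stratified incidence tables, group-comparison tests with Bonferroni
    post hoc, logistic models with unstandardized and standardized
    coefficients, Little's MCAR test, and a calibrated synthetic-cohort
    generator that makes every stage testable without access to the original
    cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
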