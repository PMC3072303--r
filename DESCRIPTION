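Package: cadscore
Title: Development of a Whole-Blood Gene Expression Classifier for
    Obstructive Coronary Artery Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable, tested implementation of the full development
    pipeline for a whole-blood RT-PCR gene expression classifier of
    obstructive coronary artery disease in non-diabetic patients:
    microarray-style normalization and quality control, per-gene
    case-control association (unpaired, sex/age-adjusted, robust, and
    matched-pair conditional logistic), Benjamini-Hochberg false
    discovery control, hypergeometric gene-set enrichment, correlation
    clustering and RT-PCR panel selection, meta-gene and ratio-term
    construction, LASSO variable selection with sex interactions, Ridge
    final fits with sex-specific age terms, leave-one-out
    cross-validated ROC evaluation, and the locked six-term, 23-gene
    score. A synthetic cohort generator emulating cell-type-driven
    co-expression and sex-dependent disease effects makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    igraph,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
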