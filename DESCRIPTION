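Package: iciscore
Title: Immune Cell Infiltration Subtyping and PCA-Based ICI Scoring for Bulk Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for characterising the immune cell infiltration (ICI)
    landscape of bulk tumor expression cohorts. Deconvolves 22 immune-cell
    fractions against an LM22-style signature matrix (nu-SVR or NNLS),
    derives ICI subtypes by resampled PAM consensus clustering with CDF/PAC
    model selection, builds an A/B gene signature from immunophenoscore-
    stratified differential expression (empirical-Bayes moderated t),
    reduces it with a Boruta-style shadow-feature selector, and computes a
    per-sample ICI score as the difference of first-principal-component
    projections on the two gene sets. Includes survival machinery
    (Kaplan-Meier, log-rank, maximally selected rank-statistic cutpoints),
    tumor mutation burden from MAF, preranked GSEA and hypergeometric
    over-representation analysis, immunotherapy-response validation, and a
    synthetic-cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    survival,
    e1071,
    pracma,
    ranger,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    mclust,
    pROC
Config/testthat/edition: 3
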