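Package: immunoconcord
Title: Concordance of Transcriptomic Immune Deconvolution with Quantitative Immunohistology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing gene-expression-based immune cell-type
    deconvolution against quantitative immunohistochemistry in solid tumors,
    motivated by the poorly infiltrated pancreatic adenocarcinoma setting.
    Aggregates deconvolution cell-type scores into IHC-equivalent composite
    scores (CD3/CD8/CD68), assesses their concordance with marker-positive
    cell densities by Spearman correlation with a cell-type-permutation
    significance test, stratifies survival by infiltration cutoffs
    (Kaplan-Meier, log-rank), discovers T-cell-infiltration gene signatures
    by per-gene class comparison, and classifies external cohorts as
    signature-enriched via z-scores. Includes a synthetic cohort generator
    with latent infiltration, zero-inflated deconvolution scores, planted
    signature genes and censored survival, plus matrix utilities (SVD
    imputation, hierarchical clustering, PCA with prediction ellipses) and
    readers and writers for the plain-text formats involved.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
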