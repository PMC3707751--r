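Package: survsig
Title: Prognostic Gene-Signature Discovery for Censored Breast-Cancer Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and validation of small prognostic gene-expression
    signatures for right-censored survival outcomes. Implements univariate Cox
    screening with false-discovery-rate control under dependence
    (Benjamini-Yekutieli), L1-penalized Cox regression fitted by cyclic
    coordinate descent with cross-validated shrinkage selection, stability
    selection over repeated stage-stratified train/test splits with a
    permutation-derived significance threshold, concordance-based comparison of
    gene, clinical and combined models, Kaplan-Meier risk stratification, and
    residual-adjustment diagnostics for sign-flipping correlated predictors.
    Includes a synthetic-cohort generator reproducing the correlation
    structure, censoring and clinical marginals the analysis assumes.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
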