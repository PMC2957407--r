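Package: sh2profiler
Title: SH2-Domain Binding Profile Analysis for Cancer Cell Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for SH2-domain phosphotyrosine binding
    profiles of cancer cell line panels: densitometric quantification of
    reverse-phase rosette arrays and molecular-weight-binned far-Western
    lanes, control-based probe and band filtering, two-way hierarchical
    clustering with uncentered correlation and complete linkage,
    permutation cluster-enrichment testing, Mann-Whitney biomarker screens
    with Storey q-value FDR control, Pearson correlation against drug
    log-IC50, four-parameter logistic IC50 estimation, and tyrosine kinase
    inhibitor perturbation fold-change analysis. Includes a seeded
    synthetic-data generator with known ground truth so the whole pipeline
    is testable without raw blot images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    digest,
    minpack.lm,
    stats,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
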