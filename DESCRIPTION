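Package: ductfield
Title: Spatial Mapping of Transcriptomic Field Cancerization Along Breast Ducts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping transcriptomic field cancerization in
    patient-matched epithelial samples taken at increasing proximity to a
    breast tumour (contralateral duct O1, duct samples D1 and D2, tumour T).
    Implements contralateral residualization of expression profiles,
    per-sample quantification of the variance explained by gene-level copy
    number, proximity classification by mutual-information feature selection
    with one-vs-rest linear support vector scorers under leave-one-patient-out
    cross-validation and micro-averaged ROC, discovery of proximity-informative
    gene modules by Ward agglomeration and bipartite spectral co-clustering
    with adjusted-Rand-index model selection, module-proximity correlation
    tables with uncapped Bonferroni adjustment, mutation-enrichment
    contingency tests, and hypergeometric pathway over-representation. A
    synthetic patient-matched cohort generator with planted gradients,
    copy-number coupling and mutation enrichment provides a parameter-recovery
    test surface for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
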