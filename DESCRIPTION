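Package: gisscreen
Title: Genome Instability Suppressor Screens and Cancer Defect Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for semi-quantitative gross chromosomal
    rearrangement (GCR) patch screens in Saccharomyces cerevisiae and for
    detecting defects in the corresponding genes in tumour cohorts.
    Converts papillae counts to categorical patch scores and GCR strain
    scores, optimises score cutoffs against fluctuation-assay rates with a
    weighted sensitivity/specificity cost function and ROC curves, compares
    discrete patch-score distributions with a Monte-Carlo
    Kolmogorov-Smirnov test, calls Genome Instability Suppressing (GIS)
    genes and cooperating GIS (cGIS) gene interactions, classifies gene
    modules by shared interacting queries, classifies per-sample gene
    defects from mutation, copy-number, expression and methylation data,
    and tests gene sets for enrichment of extreme tumour-suppressor scores
    and of length-normalised mutation burden by randomisation. A synthetic
    data generator with known ground truth stands in for strain
    collections and tumour cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
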