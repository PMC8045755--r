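Package: histomorph
Title: Nucleus Morphometry and Prognostic Modelling from H&E Histology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end computational-pathology pipeline for gastric
    adenocarcinoma and similar solid tumours. Segments cell nuclei from
    H&E-stained image tiles after stain normalization, measures ten
    cell-level morphometric features per nucleus (size, shape, colour, and
    Delaunay-graph neighbour distances), and aggregates them into a
    150-dimensional patient-level feature vector using cohort-shared
    histogram bins. Downstream modules test each feature for association
    with binary somatic-mutation status (Mann-Whitney U with
    Benjamini-Hochberg correction), build a leave-one-out cross-validated
    lasso-penalized Cox prognostic risk index with log-rank feature
    pre-filtering, and integrate prognostic features with gene expression
    via Spearman correlation and hypergeometric gene-set enrichment. A
    synthetic-data module generates ground-truthed image tiles, cohorts
    with planted mutation and survival effects, and expression matrices
    for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    glmnet,
    deldir,
    EBImage,
    png,
    tiff,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
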