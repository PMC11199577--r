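Package: blockpls
Title: Multi-Block Sparse PLS-DA Integration of Multi-Omics Data with
    Persistence Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Supervised integration of RNA-seq expression, DNA methylation,
    genotype and phenotype data for binary disease prediction. Implements a
    bespoke NIPALS-based (sparse) PLS-DA engine, a multi-block sparse PLS-DA
    (DIABLO-style) solver with consensus-centroid prediction, persistence
    (stability) feature selection over repeated unstratified hold-out
    train/test splits, classifier evaluation (accuracy, ROC AUC, Matthews
    correlation coefficient) against a majority-class baseline, and
    cross-omics interpretation outputs (circle coordinates, association
    matrices, correlation networks, clustered heatmap orderings). Includes a
    seeded synthetic multi-omics cohort generator with planted ground truth,
    and Methods-level preprocessing: M-value transform, median-of-ratios
    count normalization, low-expression filtering and genotype quality
    control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    DESeq2,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
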