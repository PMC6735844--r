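Package: cellcore
Title: Quality-Tracked Preliminary Analysis of Single-Cell RNA-Seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A streamlined toolkit for the preliminary analysis of single-cell
    RNA-seq count matrices. Provides a quality-tracked expression container
    (an extension of SingleCellExperiment whose per-cell and per-gene QC
    metrics are recomputed after every mutation and whose operations are
    logged), median-absolute-deviation and control-gene cell filtering,
    low-abundance gene filtering, batch scale-factor normalization,
    relative-log-expression size factors adapted to zero-inflated counts,
    principal component analysis with variance-explained reporting,
    stability-selected hierarchical clustering (CORE: windowed dendrogram
    cuts scored by the adjusted Rand index), a combined discrete-plus-
    continuous likelihood-ratio test for differential expression, a
    zero-inflated negative-binomial count simulator for validation, and a
    lossless on-disk bundle format for interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
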