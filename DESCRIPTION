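Package: picsim
Title: Simulation of Paired-Insertion Count Matrices for Single-Cell ATAC-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates interpretable distributional parameters (log-normal
    library sizes, Weibull/gamma peak means, per-cell sparsity, common
    biological coefficient of variation) from a peak-by-cell paired-insertion
    count matrix and simulates realistic synthetic scATAC-seq count matrices:
    a single homogeneous cell type, multiple cell groups with differential
    accessibility and technical batches, and population-scale cohorts with
    genotype-driven chromatin-accessibility-QTL (caQTL) effects. Ships
    real-versus-simulated diagnostic metrics, mapper-ready pseudobulk export
    with ground-truth tables, and fully synthetic fixture generators
    (counts, Hardy-Weinberg genotypes, peak annotations) so the whole
    pipeline runs without external data.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3), SingleCellExperiment
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    edgeR,
    fitdistrplus,
    jsonlite,
    rtracklayer,
    vcfR,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    cluster
biocViews: SingleCell, Epigenetics, ATACSeq, Software, Simulation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
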