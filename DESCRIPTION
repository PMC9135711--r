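Package: reglink
Title: Regulatory Linkage Analysis for Paired Single-Cell ATAC and RNA Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for regulatory analysis of paired single-cell chromatin
    accessibility (scATAC-seq) and gene expression (scRNA-seq) data from a
    case/control design: quality-control filtering, gene activity scores,
    bias-corrected transcription-factor motif deviation scoring with
    GC/accessibility-matched background peaks, Tn5 footprint aggregation with
    insertion-bias correction, Wilcoxon/Benjamini-Hochberg differential
    accessibility and expression, hypergeometric motif enrichment, gene-set
    signature scores, permutation-based ligand-receptor testing,
    centroid-backbone pseudotime, pseudobulk peak-to-gene linkage and
    co-accessibility, TF-target networks with a differential linkage score,
    GWAS SNP overlap, tissue peak-set deviation enrichment, and Kaplan-Meier
    survival stratification of a patient cohort by a target-gene signature.
    Includes a synthetic paired-multiome generator with planted ground truth
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
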