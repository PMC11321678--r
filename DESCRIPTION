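Package: mbcircuits
Title: Regulatory Circuits from Single-Cell Chromatin Accessibility in Medulloblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse single-cell ATAC-seq of medulloblastoma: per-cell
    quality control on fragment files, genome-tiled insertion-count and gene
    activity score matrices, copy-number inference from GC-matched
    reference-corrected sliding-window coverage, per-cell transcription-factor
    motif deviations with matched-background z-scores, cis-co-accessibility
    networks linking candidate regulatory elements to genes, positive-regulator
    detection and TF-to-neurotransmitter-receptor network assembly, and an
    expression-cohort subgroup classifier built on neurotransmitter-receptor
    genes. Includes a synthetic-data generator with planted clonal copy-number
    segments, GC coverage bias and TF-driven accessibility programs, so the
    whole pipeline is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    cluster,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
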