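Package: umidedup
Title: UMI-Aware Read Deduplication and Error Correction
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deduplication and error correction of unique molecular identifier
    (UMI) tagged sequencing reads. Reads in coordinate-sorted BAM files are
    grouped by soft-clip-corrected mapping position and their UMIs are
    error-corrected by directional, acyclic or raw clustering over a BK-tree
    index under Hamming distance. Each UMI cluster is collapsed to a single
    representative read chosen by majority vote on the full read sequence,
    independent of mapping quality; sparse clusters of one or two reads are
    discarded by default, and overlapping mate pairs can be merged. The package
    also ships a PCR/sequencing simulator (template populations with planted
    single-nucleotide variants at fixed allele frequencies, stochastic-branching
    PCR with per-base errors, UMI sequencing errors) and an evaluation layer
    (pileup variant calling, precision/recall/F1 scoring against simulated
    truth, frequency concordance and UMI cluster-structure statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    VariantAnnotation,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    SummarizedExperiment
biocViews: Sequencing, Alignment, Preprocessing, QualityControl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
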