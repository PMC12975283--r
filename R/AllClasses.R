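#' UmiClustering: a partition of UMI strings into error-corrected clusters
#'
#' The result of [clusterUmis()]. UMIs are stored in processing order
#' (descending read count, ties broken lexicographically) together with an
#' integer cluster membership. The first UMI of each cluster in this order is
#' its root, the highest-count member.
#'
#' @slot umi character vector of UMI strings (processing order).
#' @slot count integer read count per UMI.
#' @slot membership integer cluster id per UMI (1..nClusters).
#' @slot method clustering method used: "directional", "acyclic" or "raw".
#' @slot maxEdits maximum Hamming distance merged.
#' @slot thresholdMultiplier abundance-rule multiplier m in
#'   `count(parent) >= m * count(child) - 1`.
#'
#' @aliases UmiClustering-class
#' @exportClass UmiClustering
setClass("UmiClustering",
    representation(
        umi = "character",
        count = "integer",
        membership = "integer",
        method = "character",
        maxEdits = "integer",
        thresholdMultiplier = "numeric"
    )
)

setValidity("UmiClustering", function(object) {
    msg <- NULL
    n <- length(object@umi)
    if (length(object@count) != n || length(object@membership) != n)
        msg <- c(msg, "umi, count and membership must have equal length")
    if (n > 0) {
        if (any(object@count < 1L))
            msg <- c(msg, "all UMI counts must be >= 1")
        k <- max(object@membership)
        if (!setequal(unique(object@membership), seq_len(k)))
            msg <- c(msg, "membership must cover 1..nClusters")
        if (length(unique(nchar(object@umi))) > 1L)
            msg <- c(msg, "all UMIs in one clustering must have equal length")
        ## root (first member in processing order) has maximal count
        first <- !duplicated(object@membership)
        rootCount <- object@count[first][object@membership]
        if (any(object@count > rootCount))
            msg <- c(msg, "cluster root must have maximal count")
    }
    if (is.null(msg)) TRUE else msg
})

#' BKTree: metric-tree index over UMI strings
#'
#' A Burkhard-Keller tree under Hamming distance, supporting k-bounded
#' neighbor queries via the triangle inequality. Built by [bkTree()]; the
#' underlying index lives in native memory and is rebuilt from `umis` if the
#' object is serialized and reloaded.
#'
#' @slot ptr external pointer to the native index.
#' @slot umis the indexed strings, in insertion order.
#'
#' @aliases BKTree-class
#' @exportClass BKTree
setClass("BKTree", representation(ptr = "ANY", umis = "character"))

#' SimConfig: parameterization of the simulated UMI benchmark
#'
#' Defaults reproduce the benchmark conditions of the validation study:
#' 30000 unique templates on a 500 bp reference carrying nine SNVs (three
#' independent variants at each of 1%, 0.1% and 0.01% allele frequency),
#' 7 PCR cycles at 0.9 per-cycle efficiency with a 1e-6 per-base replication
#' error rate, 10 bp UMIs read with a 0.5% per-base sequencing error, and
#' 2 x 250 bp amplicon reads tiling the template exactly.
#'
#' @slot referenceLength reference length in bp (used when `reference` is empty).
#' @slot reference explicit reference sequence, or "" to generate one.
#' @slot nTemplates number of unique template molecules N.
#' @slot snvFreqs allele-frequency strata for planted SNVs.
#' @slot snvPerFreq number of independent SNVs per stratum.
#' @slot snvTable optional explicit data.frame(pos, alt, freq) (0-based pos);
#'   overrides `snvFreqs`/`snvPerFreq` when non-empty.
#' @slot pcrCycles number of PCR cycles c.
#' @slot pcrEfficiency per-cycle copy probability e (expected (1+e)-fold growth).
#' @slot pcrErrorRate per-base error probability per replication event (mu).
#' @slot errorModel "replication" (errors drawn per final molecule, scaled by
#'   its replication count) or "lineage" (errors drawn per copy event and
#'   inherited by descendants).
#' @slot umiLength UMI length L in bases.
#' @slot umiErrorRate per-base UMI sequencing substitution rate (epsilon).
#' @slot readLength sequenced read length R.
#' @slot seqErrorRate per-base read sequencing substitution rate.
#' @slot fragment "amplicon" (fragment = whole template) or "normal"
#'   (length ~ Normal(fragmentMean, fragmentSd) truncated to `[R, template]`).
#' @slot fragmentMean,fragmentSd fragment-size distribution parameters.
#' @slot yield fraction of PCR-pool molecules sampled for sequencing.
#'
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        referenceLength = "integer",
        reference = "character",
        nTemplates = "integer",
        snvFreqs = "numeric",
        snvPerFreq = "integer",
        snvTable = "data.frame",
        pcrCycles = "integer",
        pcrEfficiency = "numeric",
        pcrErrorRate = "numeric",
        errorModel = "character",
        umiLength = "integer",
        umiErrorRate = "numeric",
        readLength = "integer",
        seqErrorRate = "numeric",
        fragment = "character",
        fragmentMean = "numeric",
        fragmentSd = "numeric",
        yield = "numeric"
    )
)

setValidity("SimConfig", function(object) {
    msg <- NULL
    e <- object@pcrEfficiency
    if (!(e > 0 && e <= 1)) msg <- c(msg, "pcrEfficiency must be in (0, 1]")
    for (nm in c("pcrErrorRate", "umiErrorRate", "seqErrorRate")) {
        v <- slot(object, nm)
        if (!(v >= 0 && v < 1)) msg <- c(msg, paste(nm, "must be in [0, 1)"))
    }
    if (object@umiLength < 1L) msg <- c(msg, "umiLength must be >= 1")
    if (object@nTemplates < 1L) msg <- c(msg, "nTemplates must be >= 1")
    if (!object@fragment %in% c("amplicon", "normal"))
        msg <- c(msg, "fragment must be 'amplicon' or 'normal'")
    if (!object@errorModel %in% c("replication", "lineage"))
        msg <- c(msg, "errorModel must be 'replication' or 'lineage'")
    if (!(object@yield > 0 && object@yield <= 1))
        msg <- c(msg, "yield must be in (0, 1]")
    if (nrow(object@snvTable) == 0L) {
        if (length(object@snvFreqs) != length(object@snvPerFreq) &&
            length(object@snvPerFreq) != 1L)
            msg <- c(msg, "snvPerFreq must match snvFreqs or have length 1")
        if (any(object@snvFreqs * object@nTemplates < 1))
            msg <- c(msg, "every planted frequency needs f * N >= 1")
    } else {
        st <- object@snvTable
        if (!all(c("pos", "alt", "freq") %in% names(st)))
            msg <- c(msg, "snvTable needs columns pos, alt, freq")
        else {
            if (anyDuplicated(st$pos))
                msg <- c(msg, "SNV positions must be distinct")
            if (any(st$freq * object@nTemplates < 1))
                msg <- c(msg, "every planted frequency needs f * N >= 1")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' UmiSimulation: a realized benchmark dataset
#'
#' Output of [simulateReads()]: the reference, the template population with
#' its UMIs and planted variants, the ground-truth variant table, and one
#' simulated read pair per sampled PCR-pool molecule (aligned-orientation
#' sequences with truth coordinates, ready to write as FASTQ or as a
#' truth-placed BAM).
#'
#' @slot config the [SimConfig-class] used.
#' @slot reference reference sequence (character).
#' @slot templates data.frame: template id, umi, fragment start/end, haplotype.
#' @slot truth [GenomicRanges::GRanges] of planted SNVs with mcols ref, alt,
#'   freq, carriers (0-based positions kept in mcols$pos0).
#' @slot reads data.table of simulated read pairs (one row per pair).
#' @slot stats list: pool size, UMI collision count, reads with UMI errors, ...
#'
#' @aliases UmiSimulation-class
#' @exportClass UmiSimulation
setClass("UmiSimulation",
    representation(
        config = "SimConfig",
        reference = "character",
        templates = "data.frame",
        truth = "ANY",
        reads = "data.frame",
        stats = "list"
    )
)

#' DedupResult: output of a deduplication run
#'
#' @slot bam path to the deduplicated, coordinate-sorted BAM.
#' @slot stats run summary (input reads, accepted, rejected-by-category,
#'   groups, clusters before/after correction, sparse clusters dropped,
#'   reads written).
#' @slot verdicts per-cluster table: group key, root UMI, reads, agreeing
#'   reads, max-MAPQ tie flag, divergence histogram fields, retained flag.
#' @slot params the effective run configuration.
#'
#' @aliases DedupResult-class
#' @exportClass DedupResult
setClass("DedupResult",
    representation(
        bam = "character",
        stats = "list",
        verdicts = "data.frame",
        params = "list"
    )
)

#' EvalMetrics: precision/recall/F1 of variant calls against simulated truth
#'
#' @slot tp,fp,fn integer counts (position + alt exact matching).
#' @slot precision,recall,f1 numeric in `[0,1]`; conventionally 0 when undefined.
#' @slot perVariant data.frame with one row per truth variant: position,
#'   ref, alt, simulated frequency, observed frequency (NA when missed).
#' @slot fpCalls data.frame of false-positive calls.
#'
#' @aliases EvalMetrics-class
#' @exportClass EvalMetrics
setClass("EvalMetrics",
    representation(
        tp = "integer",
        fp = "integer",
        fn = "integer",
        precision = "numeric",
        recall = "numeric",
        f1 = "numeric",
        perVariant = "data.frame",
        fpCalls = "data.frame"
    )
)
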