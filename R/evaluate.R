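#' Call substitution variants by pileup
#'
#' Counts base occurrences per reference position from the aligned (merged
#' or unmerged) reads of a BAM and emits every non-reference allele whose
#' read support reaches `minAltReads`. Substitutions only; insertions and
#' deletions are ignored. This is a deliberately threshold-free caller: with
#' the default `minAltReads = 1`, any alternate evidence becomes a call, so
#' deduplication quality is measured without a frequency floor hiding
#' singleton-driven false positives.
#'
#' @param bam path to an aligned BAM (indexed or indexable).
#' @param reference the reference sequence (character scalar or
#'   [Biostrings::DNAString]).
#' @param refName expected reference (contig) name; default: the single
#'   contig in the BAM header. A contig/length mismatch with the header is
#'   fatal.
#' @param minAltReads minimum alt read count to emit a call (default 1).
#' @return a `data.frame` with one row per called variant: `pos0` (0-based
#'   position), `ref`, `alt`, `altCount`, `depth`, `freq` = altCount/depth.
#' @export
pileupVariants <- function(bam, reference, refName = NULL, minAltReads = 1L) {
    reference <- toupper(as.character(reference))
    targets <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
    if (is.null(refName)) {
        if (length(targets) != 1L)
            stop("BAM has ", length(targets),
                 " contigs; give refName to select one")
        refName <- names(targets)
    }
    if (!refName %in% names(targets))
        stop("contig '", refName, "' absent from the BAM header")
    if (targets[[refName]] != nchar(reference))
        stop("reference length (", nchar(reference),
             ") does not match BAM contig length (", targets[[refName]], ")")

    pu <- Rsamtools::pileup(bam,
        pileupParam = Rsamtools::PileupParam(
            max_depth = 1000000L, min_base_quality = 0L, min_mapq = 0L,
            min_nucleotide_depth = 1L, distinguish_strands = FALSE,
            distinguish_nucleotides = TRUE, include_deletions = FALSE,
            include_insertions = FALSE))
    pu <- as.data.table(pu)
    if (nrow(pu) > 0L) pu <- pu[as.character(seqnames) == refName]
    if (nrow(pu) == 0L)
        return(data.frame(pos0 = integer(0), ref = character(0),
                          alt = character(0), altCount = integer(0),
                          depth = integer(0), freq = numeric(0)))
    pu <- pu[nucleotide %in% c("A", "C", "G", "T")]
    pu[, nucleotide := as.character(nucleotide)]
    pu[, depth := sum(count), by = pos]
    pu[, ref := substr(rep(reference, .N), pos, pos)]
    calls <- pu[nucleotide != ref & count >= as.integer(minAltReads)]
    setorder(calls, pos, nucleotide)
    data.frame(pos0 = calls$pos - 1L, ref = calls$ref,
               alt = calls$nucleotide, altCount = calls$count,
               depth = calls$depth, freq = calls$count / calls$depth)
}

.truthTable <- function(truth) {
    if (is(truth, "GRanges")) {
        m <- S4Vectors::mcols(truth)
        data.table(pos0 = if ("pos0" %in% names(m)) m$pos0
                          else IRanges::start(truth) - 1L,
                   ref = as.character(m$ref), alt = as.character(m$alt),
                   freq = m$freq)
    } else {
        dt <- as.data.table(truth)
        if (!"pos0" %in% names(dt) && "pos" %in% names(dt))
            setnames(dt, "pos", "pos0")
        dt[, .(pos0 = as.integer(pos0), ref = as.character(ref),
               alt = as.character(alt), freq = as.numeric(freq))]
    }
}

#' Score variant calls against simulated truth
#'
#' Position-exact matching: a call is a true positive iff its 0-based
#' position \emph{and} alternate allele both match a truth variant.
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = 2PR/(P+R); by
#' convention each is 0 when its denominator is 0.
#'
#' @param calls data.frame from [pileupVariants()].
#' @param truth the truth variants: [simTruth()] output (a GRanges) or a
#'   data.frame with `pos0` (or `pos`), `ref`, `alt`, `freq`.
#' @return an [EvalMetrics-class].
#' @export
scoreCalls <- function(calls, truth) {
    tt <- .truthTable(truth)
    calls <- as.data.table(calls)
    callKey <- if (nrow(calls)) paste(calls$pos0, calls$alt) else character(0)
    truthKey <- paste(tt$pos0, tt$alt)
    isTp <- callKey %in% truthKey
    tp <- sum(isTp)
    fp <- sum(!isTp)
    fn <- nrow(tt) - tp
    precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
        2 * precision * recall / (precision + recall)
    } else 0

    perVariant <- copy(tt)
    i <- match(truthKey, callKey)
    perVariant[, obsFreq := ifelse(is.na(i), NA_real_, calls$freq[i])]
    perVariant[, detected := !is.na(i)]
    setnames(perVariant, "freq", "simFreq")

    new("EvalMetrics",
        tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
        precision = precision, recall = recall, f1 = f1,
        perVariant = as.data.frame(perVariant),
        fpCalls = as.data.frame(calls[!isTp]))
}

#' @rdname EvalMetrics-accessors
#' @param x an `EvalMetrics`.
#' @export
setMethod("metricsTable", "EvalMetrics", function(x) {
    data.frame(tp = x@tp, fp = x@fp, fn = x@fn,
               precision = x@precision, recall = x@recall, f1 = x@f1)
})

setMethod("show", "EvalMetrics", function(object) {
    cat(sprintf(
        "EvalMetrics: TP=%d FP=%d FN=%d  precision=%.4g recall=%.4g F1=%.4g\n",
        object@tp, object@fp, object@fn, object@precision, object@recall,
        object@f1))
})

#' Observed-vs-simulated frequency concordance
#'
#' Groups the true variants by their simulated allele frequency and reports,
#' per stratum, how many were detected, the mean observed frequency among
#' the detected, and the relative bias (observed - simulated)/simulated.
#' Strata with no detected variant are reported with `NA` summaries rather
#' than dropped or NaN-propagated.
#'
#' @param metrics an [EvalMetrics-class] from [scoreCalls()].
#' @return data.frame: simFreq, nTruth, nDetected, meanObsFreq, bias.
#' @export
frequencyConcordance <- function(metrics) {
    pv <- as.data.table(metrics@perVariant)
    out <- pv[, .(
        nTruth = .N,
        nDetected = sum(detected),
        meanObsFreq = if (any(detected)) mean(obsFreq[detected]) else NA_real_
    ), by = simFreq]
    out[, bias := (meanObsFreq - simFreq) / simFreq]
    setorder(out, -simFreq)
    as.data.frame(out)
}

#' UMI cluster-structure statistics
#'
#' Summaries of the clusters formed during deduplication: the cluster-size
#' histogram and maximum, the fraction of reads whose full sequence differs
#' from their cluster's dominant sequence (with the mismatch-count
#' histogram; reads of deviant length fall in bucket `"other"`), the
#' fraction of clusters in which two or more reads tie at the maximum MAPQ
#' (the ambiguity that MAPQ-based representative selection cannot resolve),
#' and the sparse-cluster fraction (clusters of one or two reads).
#'
#' @param x a [DedupResult-class].
#' @return a list with elements `sizeHistogram`, `maxClusterSize`,
#'   `fracReadsDivergent`, `divergenceHistogram`, `fracMaxMapqTie`,
#'   `sparseFraction`, `nClusters`.
#' @export
clusterStats <- function(x) {
    stopifnot(is(x, "DedupResult"))
    v <- as.data.table(x@verdicts)
    if (nrow(v) == 0L)
        return(list(sizeHistogram = table(integer(0)), maxClusterSize = 0L,
                    fracReadsDivergent = NA_real_,
                    divergenceHistogram = integer(0),
                    fracMaxMapqTie = NA_real_, sparseFraction = NA_real_,
                    nClusters = 0L))
    list(sizeHistogram = table(v$nReads),
         maxClusterSize = max(v$nReads),
         fracReadsDivergent = sum(v$nReads - v$nAgreeing) / sum(v$nReads),
         divergenceHistogram = x@stats$divergenceHistogram,
         fracMaxMapqTie = mean(v$maxMapqTie & v$nReads >= 2L),
         sparseFraction = mean(v$nReads <= 2L),
         nClusters = nrow(v))
}
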