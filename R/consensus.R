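#' Majority-rule representative of a UMI cluster
#'
#' Determines the cluster consensus by majority vote on the \emph{full read
#' sequence}: the dominant sequence is the exact sequence string observed
#' most often among the cluster's reads (ties broken toward the
#' lexicographically smallest sequence, for determinism). An existing read
#' is then emitted as the representative — among the reads carrying the
#' dominant sequence, the one with the highest MAPQ and then the
#' lexicographically smallest name. Mapping quality is never used to choose
#' the \emph{sequence}, only to pick the record that carries it; this avoids
#' the arbitrary tie-breaking that MAPQ-based selection suffers when many
#' reads share the maximum MAPQ.
#'
#' @param seqs character vector: the cluster's read sequences.
#' @param mapq integer vector of mapping qualities (default all 0).
#' @param names read names (default positional).
#' @return a list:
#'   \item{dominant}{the winning sequence string}
#'   \item{repIndex}{index of the representative read}
#'   \item{nReads}{cluster size}
#'   \item{nAgreeing}{reads whose sequence equals the dominant}
#'   \item{divergence}{named integer vector: Hamming mismatch count vs the
#'     dominant sequence -> number of reads (unequal lengths in bucket
#'     `"other"`)}
#' @examples
#' majorityRepresentative(c("ACGT", "ACGT", "ACGT", "ACGA"))
#' @export
majorityRepresentative <- function(seqs, mapq = NULL, names = NULL) {
    n <- length(seqs)
    if (n == 0L) stop("cluster must be non-empty")
    if (is.null(mapq)) mapq <- integer(n)
    if (is.null(names)) names <- as.character(seq_len(n))
    counts <- table(seqs)
    top <- max(counts)
    cand <- sort(names(counts)[counts == top], method = "radix")
    dominant <- cand[1L]
    agree <- which(seqs == dominant)
    agree <- agree[order(-mapq[agree], method_radix_order(names[agree]))]
    repIndex <- agree[1L]
    d <- hammingDistance(seqs, dominant, allowUnequal = TRUE)
    div <- table(ifelse(is.na(d), "other", as.character(d)))
    div <- setNames(as.integer(div), names(div))
    div <- div[names(div) != "0"]
    list(dominant = dominant, repIndex = repIndex, nReads = n,
         nAgreeing = length(agree), divergence = div)
}

#' Filter sparse read clusters
#'
#' UMI clusters with one or two reads after correction carry too little
#' depth for error correction and largely arise from UMI
#' synthesis/sequencing errors; by default they are discarded to minimize
#' noise. Retention can be enabled to maximize sensitivity.
#'
#' @param verdicts a data.frame with an `nReads` column (one row per
#'   cluster), e.g. [clusterVerdicts()] output.
#' @param keepSingletons if `TRUE`, retain all clusters regardless of size.
#' @param minReads smallest retained cluster size when filtering (default 3,
#'   i.e. clusters of one or two reads are dropped).
#' @return the input with a logical `retained` column set; attributes
#'   `nDropped` and `nRetained` carry the counts.
#' @export
filterSparse <- function(verdicts, keepSingletons = FALSE, minReads = 3L) {
    verdicts <- as.data.table(verdicts)
    if (nrow(verdicts) == 0L) {
        verdicts[, retained := logical(0)]
    } else {
        verdicts[, retained := keepSingletons | nReads >= as.integer(minReads)]
    }
    setattr(verdicts, "nDropped", sum(!verdicts$retained))
    setattr(verdicts, "nRetained", sum(verdicts$retained))
    verdicts[]
}

.phred <- function(qual) utf8ToInt(qual) - 33L
.phredChr <- function(q) intToUtf8(pmax(q, 0L) + 33L)

#' Merge overlapping mate pairs into one fragment-spanning read
#'
#' Locates the mate overlap by alignment coordinates (no indel-aware
#' realignment: both reads must be fully aligned, M-only CIGARs). In the
#' overlap, agreeing bases keep the higher of the two qualities; at
#' disagreements the higher-quality base wins (ties go to read 1) and the
#' resulting quality is the absolute quality difference. Flanking bases are
#' copied verbatim. Merging avoids the incomplete deduplication that
#' strand-specific mapping differences otherwise cause for paired data.
#'
#' @param start1,start2 0-based aligned starts of the two mates.
#' @param seq1,seq2 aligned-orientation sequences.
#' @param qual1,qual2 Phred+33 quality strings.
#' @param maxGap largest tolerated gap between abutting mates (default 0,
#'   i.e. spans must overlap or abut). Pairs further apart are left
#'   unmerged (`NULL` is returned; callers count them).
#' @return `NULL` when unmergeable, else a list with `start`, `seq`, `qual`
#'   and `overlap` (the overlap width in bases). The merged length is
#'   `len1 + len2 - overlap`.
#' @examples
#' m <- mergePair(0L, "ACGT", "IIII", 2L, "GTAA", "IIII")
#' m$seq  # "ACGTAA"
#' @export
mergePair <- function(start1, seq1, qual1, start2, seq2, qual2,
                      maxGap = 0L) {
    l1 <- nchar(seq1); l2 <- nchar(seq2)
    e1 <- start1 + l1; e2 <- start2 + l2
    ## identify left/right by coordinate; read-1 priority on base ties is
    ## kept regardless of orientation
    if (start1 <= start2) {
        sL <- start1; eL <- e1; seqL <- seq1; quL <- qual1; leftIs1 <- TRUE
        sR <- start2; eR <- e2; seqR <- seq2; quR <- qual2
    } else {
        sL <- start2; eL <- e2; seqL <- seq2; quL <- qual2; leftIs1 <- FALSE
        sR <- start1; eR <- e1; seqR <- seq1; quR <- qual1
    }
    gap <- sR - eL
    if (gap > maxGap) return(NULL)
    overlap <- max(0L, min(eL, eR) - sR)
    if (overlap == 0L) {
        return(list(start = sL, seq = paste0(seqL, seqR),
                    qual = paste0(quL, quR), overlap = 0L))
    }
    ## overlap spans [sR, sR + overlap)
    oL <- substr(seqL, sR - sL + 1L, sR - sL + overlap)
    oR <- substr(seqR, 1L, overlap)
    qL <- .phred(substr(quL, sR - sL + 1L, sR - sL + overlap))
    qR <- .phred(substr(quR, 1L, overlap))
    bL <- strsplit(oL, "", fixed = TRUE)[[1L]]
    bR <- strsplit(oR, "", fixed = TRUE)[[1L]]
    agree <- bL == bR
    ## disagreement: higher quality wins; tie -> read 1's base
    takeL <- agree | (qL > qR) | (qL == qR & leftIs1)
    cons <- ifelse(takeL, bL, bR)
    consQ <- ifelse(agree, pmax(qL, qR), abs(qL - qR))
    leftFlank <- substr(seqL, 1L, sR - sL)
    leftFlankQ <- substr(quL, 1L, sR - sL)
    if (eR >= eL) {
        rightFlank <- substring(seqR, overlap + 1L)
        rightFlankQ <- substring(quR, overlap + 1L)
    } else {
        ## right read contained in left: trailing flank comes from left
        rightFlank <- substring(seqL, sR - sL + overlap + 1L)
        rightFlankQ <- substring(quL, sR - sL + overlap + 1L)
    }
    list(start = sL,
         seq = paste0(leftFlank, paste(cons, collapse = ""), rightFlank),
         qual = paste0(leftFlankQ, .phredChr(consQ), rightFlankQ),
         overlap = overlap)
}

## Vectorized pair merging for the pipeline. Assumes M-only alignment layout
## produced by the simulator/consensus path (start1 <= start2, eR >= eL).
## Rows where the overlap bases and qualities agree take a fast string path;
## the rest fall back to mergePair(). Pairs separated by more than maxGap
## are flagged unmerged.
.mergeBatch <- function(start1, seq1, qual1, start2, seq2, qual2,
                        maxGap = 0L) {
    n <- length(seq1)
    l1 <- nchar(seq1); l2 <- nchar(seq2)
    e1 <- start1 + l1
    gap <- start2 - e1
    mergeable <- gap <= maxGap & start1 <= start2 & (start2 + l2) >= e1
    overlap <- pmax(0L, pmin(e1 - start2, l2))
    out <- data.table(start = start1, seq = NA_character_,
                      qual = NA_character_, merged = FALSE,
                      overlap = overlap)
    if (!any(mergeable)) return(out)

    idx <- which(mergeable)
    o <- overlap[idx]
    oL <- substr(seq1[idx], start2[idx] - start1[idx] + 1L, l1[idx])
    oR <- substr(seq2[idx], 1L, o)
    qoL <- substr(qual1[idx], start2[idx] - start1[idx] + 1L, l1[idx])
    qoR <- substr(qual2[idx], 1L, o)
    fast <- oL == oR & qoL == qoR
    fi <- idx[fast]
    if (length(fi)) {
        out$seq[fi] <- paste0(seq1[fi], substring(seq2[fi], overlap[fi] + 1L))
        out$qual[fi] <- paste0(qual1[fi], substring(qual2[fi], overlap[fi] + 1L))
        out$merged[fi] <- TRUE
    }
    for (i in idx[!fast]) {
        m <- mergePair(start1[i], seq1[i], qual1[i],
                       start2[i], seq2[i], qual2[i], maxGap = maxGap)
        if (!is.null(m)) {
            out$start[i] <- m$start
            out$seq[i] <- m$seq
            out$qual[i] <- m$qual
            out$merged[i] <- TRUE
        }
    }
    out
}

#' Stratify a position group by exact read length
#'
#' Splits the members of one position group into sub-groups of identical
#' read length; UMI clustering then runs per stratum. This addresses
#' variable-length reads common in shotgun libraries, where equal mapping
#' coordinates can still mix fragments of different lengths.
#'
#' @param lengths integer vector of read lengths (or a data.frame with a
#'   `readLen` column).
#' @return a named list of integer index vectors, one per distinct length
#'   (empty list for empty input).
#' @export
stratifyByLength <- function(lengths) {
    if (is.data.frame(lengths)) lengths <- lengths$readLen
    if (length(lengths) == 0L) return(list())
    split(seq_along(lengths), lengths)
}
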