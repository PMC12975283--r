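#' Soft-clip-corrected 5' template start
#'
#' Infers where the sequenced template actually started, undoing soft
#' clipping so that adapter-trimmed or quality-clipped reads from the same
#' molecule group together. On the forward strand this is `POS` minus the
#' leading soft clip; on the reverse strand it is the rightmost template
#' base: `POS` + reference-consumed length + trailing soft clip - 1.
#' Coordinates are 0-based throughout the package interior.
#'
#' @param pos 0-based leftmost mapping position.
#' @param cigar CIGAR strings.
#' @param strand `"+"`/`"-"` (or a factor from [Rsamtools::scanBam()]).
#' @return integer vector of corrected starts; `NA` for unparseable CIGARs
#'   (callers reject and count those records).
#' @examples
#' correctedStart(100L, "5S70M", "+")   # 95
#' correctedStart(100L, "70M", "+")     # 100
#' correctedStart(100L, "70M5S", "-")   # 174
#' @export
correctedStart <- function(pos, cigar, strand) {
    cigar <- as.character(cigar)
    strand <- as.character(strand)
    u <- unique(cigar)
    info <- .parseCigars(u)
    i <- match(cigar, u)
    lead <- info$lead[i]
    trail <- info$trail[i]
    refw <- info$refw[i]
    out <- ifelse(strand == "-",
                  pos + refw + trail - 1L,
                  pos - lead)
    out[is.na(refw)] <- NA_integer_
    as.integer(out)
}

## lead/trail soft clips and reference-consumed width per unique CIGAR
.parseCigars <- function(cig) {
    n <- length(cig)
    lead <- trail <- refw <- integer(n)
    ok <- grepl("^([0-9]+[MIDNSHP=X])+$", cig)
    lead[!ok] <- trail[!ok] <- refw[!ok] <- NA_integer_
    if (any(ok)) {
        lens <- regmatches(cig[ok], gregexpr("[0-9]+", cig[ok]))
        opsl <- regmatches(cig[ok], gregexpr("[MIDNSHP=X]", cig[ok]))
        res <- mapply(function(l, o) {
            l <- as.integer(l)
            refConsuming <- o %in% c("M", "D", "N", "=", "X")
            nonclip <- which(!o %in% c("S", "H"))
            if (length(nonclip) == 0L) return(c(NA_integer_, NA, NA))
            ld <- if (o[1L] == "S") l[1L] else if (o[1L] == "H" &&
                length(o) > 1L && o[2L] == "S") l[2L] else 0L
            k <- length(o)
            tr <- if (o[k] == "S") l[k] else if (o[k] == "H" && k > 1L &&
                o[k - 1L] == "S") l[k - 1L] else 0L
            c(ld, tr, sum(l[refConsuming]))
        }, lens, opsl)
        lead[ok] <- res[1L, ]
        trail[ok] <- res[2L, ]
        refw[ok] <- res[3L, ]
    }
    list(lead = lead, trail = trail, refw = refw)
}

#' Read an alignment file into the grouping table
#'
#' Streams a coordinate-sorted BAM (or SAM) and returns the accepted primary
#' alignments as a `data.table`, with the UMI parsed from the read name and
#' the soft-clip-corrected 5' start computed. Secondary, supplementary and
#' unmapped records are dropped and counted, as are records whose name
#' carries no UMI or whose CIGAR cannot be parsed. Input that is not
#' coordinate-sorted (a position regression within one reference) is a fatal
#' error.
#'
#' @param file path to a BAM (or SAM with header) file.
#' @param separator UMI separator in read names (default `"_"`).
#' @return a list with elements
#'   \item{reads}{data.table: qname, umi, flag, rname, strand, pos (0-based),
#'     corrStart, readLen, mapq, cigar, seq, qual}
#'   \item{counts}{named list of record counts: input, accepted, unmapped,
#'     secondary, supplementary, noUmi, badCigar}
#'   \item{targets}{named integer vector of reference lengths (header).}
#' @export
readAlignments <- function(file, separator = "_") {
    file <- .asBamFile(file)
    hdr <- Rsamtools::scanBamHeader(file)[[1L]]
    targets <- hdr$targets
    param <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "strand", "pos", "mapq",
                 "cigar", "seq", "qual"))
    b <- Rsamtools::scanBam(file, param = param)[[1L]]
    nin <- length(b$qname)
    counts <- list(input = nin, accepted = 0L, unmapped = 0L,
                   secondary = 0L, supplementary = 0L, noUmi = 0L,
                   badCigar = 0L)
    if (nin == 0L) {
        return(list(reads = data.table(), counts = counts, targets = targets))
    }
    flag <- b$flag
    unmapped <- bitwAnd(flag, 4L) > 0L
    secondary <- bitwAnd(flag, 256L) > 0L
    supplementary <- bitwAnd(flag, 2048L) > 0L
    keep <- !(unmapped | secondary | supplementary)
    counts$unmapped <- sum(unmapped)
    counts$secondary <- sum(secondary & !unmapped)
    counts$supplementary <- sum(supplementary & !unmapped & !secondary)

    dt <- data.table(
        qname = b$qname[keep],
        flag = flag[keep],
        rname = as.character(b$rname[keep]),
        strand = as.character(b$strand[keep]),
        pos = b$pos[keep] - 1L,           # 0-based interior convention
        mapq = b$mapq[keep],
        cigar = b$cigar[keep],
        seq = as.character(b$seq[keep]),
        qual = as.character(b$qual[keep]))

    ## sortedness: positions must be non-decreasing within each reference
    if (nrow(dt) > 1L) {
        reg <- dt[, any(diff(pos) < 0L), by = rname][V1 == TRUE]
        if (nrow(reg) > 0L)
            stop("input is not coordinate-sorted (position regression on ",
                 paste(reg$rname, collapse = ", "), ")")
    }

    dt[, umi := parseUmi(qname, separator)]
    noUmi <- is.na(dt$umi)
    counts$noUmi <- sum(noUmi)
    if (any(noUmi)) {
        warning(counts$noUmi, " record(s) without a parseable UMI were dropped")
        dt <- dt[!noUmi]
    }
    dt[, corrStart := correctedStart(pos, cigar, strand)]
    badCigar <- is.na(dt$corrStart)
    counts$badCigar <- sum(badCigar)
    if (any(badCigar)) {
        warning(counts$badCigar, " record(s) with unparseable CIGAR were dropped")
        dt <- dt[!badCigar]
    }
    dt[, readLen := nchar(seq)]
    counts$accepted <- nrow(dt)
    list(reads = dt, counts = counts, targets = targets)
}

.asBamFile <- function(file) {
    if (grepl("\\.sam$", file)) {
        dest <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                                 indexDestination = TRUE)
        return(dest)
    }
    file
}

#' Partition accepted alignments into position groups
#'
#' Assigns every record to the genomic grouping key that is the unit of UMI
#' clustering: reference, soft-clip-corrected 5' start, strand (optional)
#' and, when `lengthStratify = TRUE`, the exact read length stratum (useful
#' for variable-length shotgun libraries). Group ids are dense integers in
#' deterministic coordinate order, so `sum(group sizes)` equals the number
#' of accepted records.
#'
#' @param reads the `reads` data.table from [readAlignments()] (or a pair
#'   table from [pairReads()], which is keyed on read 1).
#' @param lengthStratify also split groups by exact read length.
#' @param ignoreStrand drop strand from the grouping key.
#' @return the input with an integer `groupKey` column added (by reference).
#' @export
positionGroups <- function(reads, lengthStratify = FALSE,
                           ignoreStrand = FALSE) {
    reads <- as.data.table(reads)
    if (nrow(reads) == 0L) {
        reads[, groupKey := integer(0)]
        return(reads[])
    }
    keys <- c("rname", "corrStart",
              if (!ignoreStrand) "strand",
              if (lengthStratify) "readLen")
    setorderv(reads, keys)
    reads[, groupKey := .GRP, by = keys]
    reads[]
}

#' Pair mates into template rows
#'
#' Joins primary read-1/read-2 records by query name into one row per
#' template, keyed for grouping on read 1's corrected 5' start and strand
#' (templates, not individual mates, are the unit of deduplication).
#' Records whose mate is absent from the accepted set are dropped and
#' counted.
#'
#' @param reads the `reads` data.table from [readAlignments()].
#' @return a list with `pairs` (data.table, one row per template: qname,
#'   umi, rname, strand, corrStart, readLen, and per-mate columns suffixed
#'   1/2) and `unpairedDropped`, the count of mate-less records.
#' @export
pairReads <- function(reads) {
    reads <- as.data.table(reads)
    if (nrow(reads) == 0L)
        return(list(pairs = data.table(), unpairedDropped = 0L))
    first <- bitwAnd(reads$flag, 64L) > 0L
    second <- bitwAnd(reads$flag, 128L) > 0L
    r1 <- reads[first & !second]
    r2 <- reads[second & !first]
    common <- intersect(r1$qname, r2$qname)
    dropped <- nrow(reads) - 2L * length(common)
    r1 <- r1[match(common, qname)]
    r2 <- r2[match(common, qname)]
    pairs <- data.table(
        qname = r1$qname, umi = r1$umi, rname = r1$rname,
        strand = r1$strand, corrStart = r1$corrStart,
        ## template read length = total sequenced bases (stratification key)
        readLen = r1$readLen + r2$readLen,
        pos1 = r1$pos, cigar1 = r1$cigar, mapq1 = r1$mapq,
        seq1 = r1$seq, qual1 = r1$qual, strand1 = r1$strand,
        pos2 = r2$pos, cigar2 = r2$cigar, mapq2 = r2$mapq,
        seq2 = r2$seq, qual2 = r2$qual, strand2 = r2$strand)
    list(pairs = pairs, unpairedDropped = as.integer(dropped))
}

## Write a SAM table + header to a coordinate-sorted, indexed BAM.
## dt columns: qname, flag, rname, pos (0-based), mapq, cigar, rnext, pnext,
## tlen, seq, qual. Returns the BAM path.
.writeBam <- function(dt, targets, destination) {
    sam <- tempfile(fileext = ".sam")
    hd <- c("@HD\tVN:1.6\tSO:unsorted",
            sprintf("@SQ\tSN:%s\tLN:%d", names(targets), as.integer(targets)),
            "@PG\tID:umidedup\tPN:umidedup")
    writeLines(hd, sam)
    if (nrow(dt) > 0L) {
        out <- data.table(
            qname = dt$qname, flag = as.integer(dt$flag),
            rname = dt$rname, pos = as.integer(dt$pos) + 1L,
            mapq = as.integer(dt$mapq), cigar = dt$cigar,
            rnext = dt$rnext, pnext = as.integer(dt$pnext),
            tlen = as.integer(dt$tlen), seq = dt$seq, qual = dt$qual)
        fwrite(out, sam, sep = "\t", append = TRUE, quote = FALSE,
               col.names = FALSE)
    }
    bam <- Rsamtools::asBam(sam, tools::file_path_sans_ext(destination),
                            overwrite = TRUE, indexDestination = TRUE)
    unlink(sam)
    bam
}

#' Write deduplicated records to a BAM file
#'
#' Emits one record per retained cluster (or one merged record per retained
#' pair when pair merging is enabled), coordinate-sorted and indexed, with
#' the reference header carried over from the input.
#'
#' @param records data.table with SAM fields `qname, flag, rname, pos`
#'   (0-based), `mapq, cigar, seq, qual` and optional `rnext, pnext, tlen`.
#' @param targets named integer vector of reference lengths.
#' @param destination output BAM path.
#' @return the path to the written BAM (invisibly).
#' @export
writeDedupBam <- function(records, targets, destination) {
    records <- as.data.table(records)
    if (nrow(records) > 0L) {
        if (!"rnext" %in% names(records)) records[, rnext := "*"]
        if (!"pnext" %in% names(records)) records[, pnext := 0L]
        if (!"tlen" %in% names(records)) records[, tlen := 0L]
    }
    invisible(.writeBam(records, targets, destination))
}
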