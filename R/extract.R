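#' Extract UMIs from reads and append them to read names
#'
#' Moves a fixed-length UMI from the 5' end of each read into the read name,
#' the convention expected by UMI-aware deduplicators: downstream tools
#' recover the UMI from the name after mapping. The UMI bases and their
#' qualities are removed from the read; the name gains `separator` + UMI
#' immediately before any whitespace/comment.
#'
#' Only fixed-length prefix patterns are supported (no mixed UMI + spacer
#' regular expressions); this covers both inline-barcode designs exercised
#' by the package. For paired data with the UMI on one mate, run this on the
#' UMI-carrying file.
#'
#' @param names,seqs,quals character vectors describing the reads.
#' @param umiLength UMI length in bases (>= 1).
#' @param separator single character joining UMI to name; must not be a
#'   valid UMI base (A, C, G, T or N).
#' @return a list with elements `names`, `seqs`, `quals`, `umis` for the
#'   accepted reads, and `rejected`, the count of reads with length <=
#'   `umiLength` (these are dropped, with a warning).
#' @examples
#' extractUmi("r1", "ACGTACGTACGTTTTT", strrep("I", 16), umiLength = 10)
#' @export
extractUmi <- function(names, seqs, quals = NULL, umiLength,
                       separator = "_") {
    .checkSeparator(separator)
    umiLength <- as.integer(umiLength)
    stopifnot(umiLength >= 1L)
    if (is.null(quals)) quals <- strrep("I", nchar(seqs))
    keep <- nchar(seqs) > umiLength
    nrej <- sum(!keep)
    if (nrej > 0L)
        warning(nrej, " read(s) shorter than or equal to the UMI length were rejected")
    names <- names[keep]; seqs <- seqs[keep]; quals <- quals[keep]
    umis <- substr(seqs, 1L, umiLength)
    res <- substr(seqs, umiLength + 1L, nchar(seqs))
    resq <- substr(quals, umiLength + 1L, nchar(quals))
    ## insert separator+UMI before any comment (first whitespace)
    hasWs <- regexpr("[ \t]", names)
    id <- ifelse(hasWs > 0L, substr(names, 1L, hasWs - 1L), names)
    comment <- ifelse(hasWs > 0L, substring(names, hasWs), "")
    list(names = paste0(id, separator, umis, comment),
         seqs = res, quals = resq, umis = umis, rejected = nrej)
}

#' Recover the UMI from a read name
#'
#' Returns the substring after the \emph{last} occurrence of `separator`,
#' which tolerates separators inside instrument read names. Paired mates
#' carry identical UMIs by construction.
#'
#' @param names character vector of read names.
#' @param separator single character (default `"_"`).
#' @param onMissing what to do when a name contains no separator: `"na"`
#'   returns `NA` for that name (callers count these as rejected records),
#'   `"error"` stops.
#' @return character vector of UMIs (`NA` where missing and `onMissing =
#'   "na"`).
#' @examples
#' parseUmi("r1_ACGTACGTAC")          # "ACGTACGTAC"
#' parseUmi("a_b_TTTT")               # "TTTT" (last occurrence)
#' @export
parseUmi <- function(names, separator = "_", onMissing = c("na", "error")) {
    onMissing <- match.arg(onMissing)
    .checkSeparator(separator)
    pos <- .lastSep(names, separator)
    missing <- pos < 0L
    if (any(missing) && onMissing == "error")
        stop(sum(missing), " read name(s) contain no UMI separator '",
             separator, "'")
    out <- rep(NA_character_, length(names))
    out[!missing] <- substring(names[!missing], pos[!missing] + 1L)
    out
}

.lastSep <- function(names, separator) {
    m <- gregexpr(separator, names, fixed = TRUE)
    vapply(m, function(p) if (p[1L] == -1L) -1L else p[length(p)], integer(1))
}

.checkSeparator <- function(separator) {
    if (nchar(separator) != 1L)
        stop("separator must be a single character")
    if (toupper(separator) %in% c("A", "C", "G", "T", "N"))
        stop("separator must not be a legal UMI base (A/C/G/T/N)")
    invisible(TRUE)
}

#' Extract UMIs from a FASTQ file
#'
#' File-level wrapper around [extractUmi()]: reads a (optionally gzipped)
#' FASTQ, moves the leading `umiLength` bases of every read into the read
#' name, and writes the residual reads to `output` (gzipped when the name
#' ends in `.gz`).
#'
#' @param input,output FASTQ paths.
#' @param umiLength UMI length in bases.
#' @param separator single character joining UMI to name.
#' @return invisibly, a list with counts `accepted` and `rejected`.
#' @export
extractUmis <- function(input, output, umiLength, separator = "_") {
    ## Biostrings warns that per-record mcols are dropped when subsetting
    ## FASTQ input; nothing we use lives there
    fq <- withCallingHandlers(
        Biostrings::readQualityScaledDNAStringSet(input),
        warning = function(w) {
            if (grepl("metadata columns", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    tagged <- extractUmi(names(fq), as.character(fq),
                         as.character(Biostrings::quality(fq)),
                         umiLength = umiLength, separator = separator)
    out <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(tagged$seqs),
        Biostrings::PhredQuality(tagged$quals))
    names(out) <- tagged$names
    Biostrings::writeQualityScaledXStringSet(
        out, output, compress = grepl("\\.gz$", output))
    invisible(list(accepted = length(out), rejected = tagged$rejected))
}
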