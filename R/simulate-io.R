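#' Write a simulation as a truth-placed, coordinate-sorted BAM
#'
#' Simulated reads carry substitutions only, so their optimal alignment is
#' their generating coordinates; the simulator therefore emits alignments
#' directly (read-mapping itself is outside the package's scope). Each read
#' pair becomes two proper-pair records (read 1 forward, read 2 reverse)
#' with M-only CIGARs, MAPQ 60 and the observed UMI in the name; the result
#' is sorted and indexed, ready for [dedupBam()].
#'
#' @param sim a [UmiSimulation-class].
#' @param destination output BAM path.
#' @param refName contig name to use (default `"amplicon"`).
#' @return the BAM path, invisibly.
#' @export
writeSimulatedBam <- function(sim, destination, refName = "amplicon") {
    r <- as.data.table(sim@reads)
    targets <- setNames(nchar(sim@reference), refName)
    if (nrow(r) == 0L)
        return(invisible(.writeBam(data.table(), targets, destination)))
    l1 <- nchar(r$seq1); l2 <- nchar(r$seq2)
    span <- (r$start2 + l2) - r$start1
    recs <- rbind(
        data.table(qname = r$qname, flag = 99L, rname = refName,
                   pos = r$start1, mapq = 60L, cigar = paste0(l1, "M"),
                   rnext = "=", pnext = r$start2 + 1L, tlen = span,
                   seq = r$seq1, qual = r$qual1),
        data.table(qname = r$qname, flag = 147L, rname = refName,
                   pos = r$start2, mapq = 60L, cigar = paste0(l2, "M"),
                   rnext = "=", pnext = r$start1 + 1L, tlen = -span,
                   seq = r$seq2, qual = r$qual2))
    invisible(.writeBam(recs, targets, destination))
}

#' Write a simulation as paired FASTQ
#'
#' Read 2 is reverse-complemented into sequencing orientation. Names carry
#' the template/molecule ids and the observed UMI as the last
#' underscore-separated token; both mates share the name.
#'
#' @param sim a [UmiSimulation-class].
#' @param r1Path,r2Path output FASTQ paths (gzipped when ending in `.gz`).
#' @return invisibly, the two paths.
#' @export
writeSimulatedFastq <- function(sim, r1Path, r2Path) {
    r <- as.data.table(sim@reads)
    s1 <- Biostrings::DNAStringSet(r$seq1)
    q1 <- Biostrings::PhredQuality(r$qual1)
    s2 <- Biostrings::reverseComplement(Biostrings::DNAStringSet(r$seq2))
    q2 <- Biostrings::PhredQuality(
        vapply(strsplit(r$qual2, ""), function(x)
            paste(rev(x), collapse = ""), character(1)))
    out1 <- Biostrings::QualityScaledDNAStringSet(s1, q1)
    out2 <- Biostrings::QualityScaledDNAStringSet(s2, q2)
    names(out1) <- names(out2) <- r$qname
    Biostrings::writeQualityScaledXStringSet(
        out1, r1Path, compress = grepl("\\.gz$", r1Path))
    Biostrings::writeQualityScaledXStringSet(
        out2, r2Path, compress = grepl("\\.gz$", r2Path))
    invisible(c(r1Path, r2Path))
}

#' Write the simulated ground truth
#'
#' Emits the planted-variant table as tab-delimited text (0-based `pos`,
#' `ref`, `alt`, `freq`, `carriers`; frequencies written in plain decimal
#' notation, never scientific) and optionally as a VCF 4.x with the
#' simulated allele frequency in the `AF` INFO field (1-based positions).
#'
#' @param sim a [UmiSimulation-class].
#' @param tsvPath output path for the tab-delimited truth table.
#' @param vcfPath optional output path for the VCF.
#' @param refName contig name used in the VCF.
#' @return invisibly, the written path(s).
#' @export
writeTruth <- function(sim, tsvPath, vcfPath = NULL, refName = "amplicon") {
    tt <- .truthTable(sim@truth)
    carriers <- S4Vectors::mcols(sim@truth)$carriers
    df <- data.frame(pos = tt$pos0, ref = tt$ref, alt = tt$alt,
                     freq = vapply(tt$freq, format, character(1),
                                   scientific = FALSE, trim = TRUE),
                     carriers = carriers)
    write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
    if (is.null(vcfPath)) return(invisible(tsvPath))

    if (nrow(df) == 0L) {
        writeLines(c("##fileformat=VCFv4.2",
                     "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"),
                   vcfPath)
        return(invisible(c(tsvPath, vcfPath)))
    }
    vr <- VariantAnnotation::VRanges(
        seqnames = refName,
        ranges = IRanges::IRanges(start = tt$pos0 + 1L, width = 1L),
        ref = tt$ref, alt = tt$alt,
        sampleNames = "simulation")
    vcf <- methods::as(vr, "VCF")
    hdr <- VariantAnnotation::header(vcf)
    VariantAnnotation::info(hdr) <- S4Vectors::DataFrame(
        Number = "A", Type = "Float",
        Description = "Simulated allele frequency", row.names = "AF")
    VariantAnnotation::header(vcf) <- hdr
    VariantAnnotation::info(vcf)$AF <- tt$freq
    VariantAnnotation::writeVcf(vcf, vcfPath)
    invisible(c(tsvPath, vcfPath))
}
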