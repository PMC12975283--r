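# Fixture builders: alignments are written as literal SAM text and
# converted to BAM, so tests control every field exactly.

sam_record <- function(qname, flag, rname, pos1, mapq, cigar, seq,
                       qual = strrep("I", nchar(seq)), rnext = "*",
                       pnext = 0L, tlen = 0L) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
            qname, flag, rname, pos1, mapq, cigar, rnext, pnext, tlen,
            seq, qual)
}

write_test_bam <- function(records, targets,
                           dest = tempfile(fileext = ".bam")) {
    sam <- tempfile(fileext = ".sam")
    header <- c("@HD\tVN:1.6",
                sprintf("@SQ\tSN:%s\tLN:%d", names(targets),
                        as.integer(targets)))
    writeLines(c(header, records), sam)
    Rsamtools::asBam(sam, sub("\\.bam$", "", dest), overwrite = TRUE,
                     indexDestination = TRUE)
}

# a zero-noise benchmark: no PCR errors, no UMI errors, no base-call
# errors; 16 bp UMIs keep distinct templates >= 2 edits apart so that all
# clustering modes resolve exactly the template families
zero_noise_sim <- function(n = 1500L, refLen = 300L, cycles = 4L,
                           seed = 11L) {
    cfg <- simConfig(referenceLength = refLen, nTemplates = n,
                     pcrCycles = cycles, pcrErrorRate = 0,
                     umiErrorRate = 0, seqErrorRate = 0,
                     umiLength = 16L, readLength = as.integer(refLen / 2),
                     snvTable = data.frame(pos = c(60, 150, 240),
                                           alt = NA,
                                           freq = c(0.02, 0.02, 0.01)))
    simulateReads(cfg, seed = seed)
}

# truth-tracked retained-cluster count: template families (by true UMI)
# with at least minReads read pairs
truth_tracked_retained <- function(sim, minReads = 3L) {
    fam <- table(simReads(sim)$umiTrue)
    sum(fam >= minReads)
}
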