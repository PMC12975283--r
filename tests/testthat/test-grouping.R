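test_that("corrected start undoes soft clipping on both strands", {
    expect_equal(correctedStart(100L, "5S70M", "+"), 95L)
    expect_equal(correctedStart(100L, "70M", "+"), 100L)
    ## reverse strand: POS + reference-consumed + trailing clip - 1
    expect_equal(correctedStart(100L, "70M5S", "-"), 174L)
    expect_equal(correctedStart(100L, "10M2D10M", "-"), 121L)
    expect_equal(correctedStart(100L, "3H2S20M", "+"), 98L)
    expect_equal(correctedStart(0L, "20M5S3H", "-"), 24L)
    ## insertions consume no reference
    expect_equal(correctedStart(10L, "5M3I5M", "-"), 19L)
    expect_true(is.na(correctedStart(10L, "*", "+")))
    expect_equal(correctedStart(c(100L, 100L), c("5S70M", "70M5S"),
                                c("+", "-")), c(95L, 174L))
})

test_that("readAlignments drops non-primary records and parses UMIs", {
    bam <- write_test_bam(c(
        sam_record("a_AAAA", 0L, "chr1", 10L, 60L, "10M", strrep("A", 10)),
        sam_record("b_CCCC", 16L, "chr1", 20L, 60L, "10M", strrep("C", 10)),
        sam_record("c_GGGG", 4L, "chr1", 0L, 0L, "*", strrep("G", 10)),
        sam_record("d_TTTT", 256L, "chr1", 30L, 0L, "10M", strrep("T", 10)),
        sam_record("e_AAAA", 2048L, "chr1", 40L, 60L, "10M", strrep("A", 10)),
        sam_record("noumi", 0L, "chr1", 50L, 60L, "10M", strrep("A", 10))),
        targets = c(chr1 = 1000L))
    expect_warning(ra <- readAlignments(bam), "UMI")
    expect_equal(ra$counts$input, 6L)
    expect_equal(ra$counts$accepted, 2L)
    expect_equal(ra$counts$unmapped, 1L)
    expect_equal(ra$counts$secondary, 1L)
    expect_equal(ra$counts$supplementary, 1L)
    expect_equal(ra$counts$noUmi, 1L)
    expect_equal(ra$reads$umi, c("AAAA", "CCCC"))
    ## 0-based positions
    expect_equal(ra$reads$pos, c(9L, 19L))
    expect_equal(ra$reads$strand, c("+", "-"))
})

test_that("unsorted input is fatal", {
    ## asBam sorts, so feed SAM records through samtools-free path: write
    ## a BAM then check detection on a deliberately unsorted SAM converted
    ## with sort disabled is not possible via asBam; instead check the
    ## detector directly on a crafted table through the exported surface
    bam <- write_test_bam(c(
        sam_record("a_AAAA", 0L, "chr1", 100L, 60L, "10M", strrep("A", 10)),
        sam_record("b_AAAA", 0L, "chr1", 10L, 60L, "10M", strrep("A", 10))),
        targets = c(chr1 = 1000L))
    ## asBam already coordinate-sorts, so this BAM is fine
    expect_silent(readAlignments(bam))
    ## the regression check itself: reuse the SAM text reader
    sam <- tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6\tSO:coordinate",
                 "@SQ\tSN:chr1\tLN:1000",
                 sam_record("a_AAAA", 0L, "chr1", 100L, 60L, "10M",
                            strrep("A", 10)),
                 sam_record("b_AAAA", 0L, "chr1", 10L, 60L, "10M",
                            strrep("A", 10))), sam)
    bam2 <- tempfile(fileext = ".bam")
    ## convert without sorting (asBam always sorts, samtools view does not)
    system2("samtools", c("view", "-b", "-o", bam2, sam))
    expect_error(readAlignments(bam2), "sorted")
})

test_that("position groups partition accepted records deterministically", {
    recs <- c(
        sam_record("r1_AAAA", 0L, "chr1", 51L, 60L, "70M", strrep("A", 70)),
        sam_record("r2_AAAT", 0L, "chr1", 56L, 60L, "5S65M", strrep("A", 70)),
        sam_record("r3_CCCC", 0L, "chr1", 51L, 60L, "70M", strrep("A", 70)),
        sam_record("r4_GGGG", 16L, "chr1", 51L, 60L, "65M5S", strrep("C", 70)),
        sam_record("r5_GGGA", 16L, "chr1", 52L, 60L, "64M6S", strrep("C", 70)),
        sam_record("r6_TTTT", 0L, "chr1", 51L, 60L, "75M", strrep("G", 75)))
    bam <- write_test_bam(recs, targets = c(chr1 = 1000L))
    ra <- readAlignments(bam)
    g <- positionGroups(ra$reads)
    ## forward corrected start 50 (r1 via 5S, r2, r3, r6), reverse 119/120
    expect_equal(sum(table(g$groupKey)), ra$counts$accepted)
    expect_equal(length(unique(g$groupKey)), 3L)
    ## strand is part of the key: 4 forward at 50, 2 reverse
    byStrand <- split(g$groupKey, g$strand)
    expect_equal(length(intersect(byStrand[["+"]], byStrand[["-"]])), 0L)
    ## ignoring strand merges reverse-strand groups only if keys collide
    g2 <- positionGroups(ra$reads, ignoreStrand = TRUE)
    expect_lte(length(unique(g2$groupKey)), 3L)
    ## length stratification splits the 75 bp read off
    g3 <- positionGroups(ra$reads, lengthStratify = TRUE)
    expect_equal(length(unique(g3$groupKey)), 4L)
    ## determinism
    expect_equal(positionGroups(ra$reads)$groupKey, g$groupKey)
})

test_that("empty input gives empty groups and a valid empty output BAM", {
    bam <- write_test_bam(character(0), targets = c(chr1 = 1000L))
    ra <- readAlignments(bam)
    expect_equal(ra$counts$accepted, 0L)
    g <- positionGroups(ra$reads)
    expect_equal(nrow(g), 0L)

    out <- tempfile(fileext = ".bam")
    writeDedupBam(data.frame(), targets = c(chr1 = 1000L), out)
    hdr <- Rsamtools::scanBamHeader(out)[[1L]]
    expect_equal(hdr$targets, c(chr1 = 1000L))
    back <- Rsamtools::scanBam(out)[[1L]]
    expect_equal(length(back$qname), 0L)
})

test_that("written records survive a BAM round trip count-exactly", {
    recs <- data.frame(
        qname = c("x_AAAA", "y_CCCC"), flag = c(0L, 16L), rname = "chr1",
        pos = c(10L, 5L), mapq = c(60L, 50L), cigar = c("4M", "4M"),
        seq = c("ACGT", "GGGG"), qual = c("IIII", "FFFF"))
    out <- tempfile(fileext = ".bam")
    writeDedupBam(recs, targets = c(chr1 = 100L), out)
    back <- Rsamtools::scanBam(out)[[1L]]
    expect_equal(length(back$qname), 2L)
    ## coordinate-sorted output
    expect_equal(back$pos, sort(recs$pos) + 1L)
    expect_setequal(as.character(back$seq), recs$seq)
})

test_that("mates pair by name and key on read 1", {
    recs <- c(
        sam_record("p1_AAAA", 99L, "chr1", 11L, 60L, "10M", strrep("A", 10),
                   rnext = "=", pnext = 31L, tlen = 30L),
        sam_record("p1_AAAA", 147L, "chr1", 31L, 60L, "10M", strrep("C", 10),
                   rnext = "=", pnext = 11L, tlen = -30L),
        sam_record("orphan_TTTT", 73L, "chr1", 41L, 60L, "10M",
                   strrep("G", 10)))
    bam <- write_test_bam(recs, targets = c(chr1 = 1000L))
    ra <- readAlignments(bam)
    pr <- pairReads(ra$reads)
    expect_equal(nrow(pr$pairs), 1L)
    expect_equal(pr$unpairedDropped, 1L)
    expect_equal(pr$pairs$corrStart, 10L)
    expect_equal(pr$pairs$strand, "+")
    expect_equal(pr$pairs$readLen, 20L)
    expect_equal(pr$pairs$seq2, strrep("C", 10))
})
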