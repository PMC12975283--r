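test_that("planted carrier counts are exact, not binomial", {
    set.seed(1)
    ref <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    p <- plantSnvs(ref, 30000L)
    expect_equal(nrow(p$snvs), 9L)
    expect_equal(sort(p$snvs$carriers), rep(c(3L, 30L, 300L), each = 3L))
    expect_equal(lengths(p$carrierSets), p$snvs$carriers)
    expect_false(anyDuplicated(p$snvs$pos0) > 0L)
    expect_true(all(p$snvs$alt != p$snvs$ref))
    ## carriers really carry, non-carriers do not
    for (i in seq_len(9L)) {
        pos <- p$snvs$pos0[i] + 1L
        carried <- substr(p$haplotypes[p$carrierSets[[i]]], pos, pos)
        expect_true(all(carried == p$snvs$alt[i]))
    }
    ## rounding: N=10000 at f=1e-4 -> exactly one carrier
    p2 <- plantSnvs(ref, 10000L, snvFreqs = 1e-4, snvPerFreq = 1L)
    expect_equal(p2$snvs$carriers, 1L)
})

test_that("degenerate SNV specs are fatal with an explanation", {
    ref <- strrep("ACGT", 50L)
    expect_error(plantSnvs(ref, 100L,
                           snvTable = data.frame(pos = c(10, 10),
                                                 alt = "A", freq = 0.5)),
                 "distinct")
    expect_error(plantSnvs(ref, 100L,
                           snvTable = data.frame(pos = 0, alt = "A",
                                                 freq = 0.5)),
                 "reference base")
    expect_error(plantSnvs(ref, 100L, snvFreqs = 1e-4, snvPerFreq = 1L),
                 "carrier")
    expect_error(simConfig(pcrEfficiency = 0), "pcrEfficiency")
    expect_error(simConfig(nTemplates = 100L, snvFreqs = 1e-4), "f \\* N")
})

test_that("UMI tagging is uniform, seeded, and counts collisions", {
    set.seed(2)
    u <- tagUmis(5000L, 10L)
    expect_equal(length(u), 5000L)
    expect_true(all(nchar(u) == 10L))
    set.seed(2)
    expect_identical(as.character(tagUmis(5000L, 10L)), as.character(u))
    ## tiny barcode space warns and counts many collisions
    expect_warning(u2 <- tagUmis(100L, 1L), "small")
    expect_gte(attr(u2, "collisions"), 90L)
    ## the benchmark design (10 bp, 30000 templates) stays quiet
    expect_silent(tagUmis(30000L, 10L))
})

test_that("PCR amplification follows the branching process law", {
    ## c = 0 is the identity
    p <- amplifyPcr(5L, 0L, 0.9)
    expect_equal(p$poolSize, 5L)
    expect_equal(p$template, 1:5)
    expect_equal(p$repl, rep(0L, 5L))
    ## e = 1 doubles deterministically: 2^3 = 8 copies of one molecule
    p <- amplifyPcr(1L, 3L, 1)
    expect_equal(p$poolSize, 8L)
    expect_equal(sort(unique(p$template)), 1L)
    ## replication counts are bounded by the cycle count
    expect_true(all(p$repl <= 3L))
    ## empirical mean vs closed form (smoke scale; the full-scale check
    ## lives in the acceptance suite)
    set.seed(8)
    sizes <- vapply(1:2000, function(i) amplifyPcr(1L, 5L, 0.9)$poolSize,
                    numeric(1))
    target <- 1.9^5
    se <- sd(sizes) / sqrt(length(sizes))
    expect_lt(abs(mean(sizes) - target), 3 * se)
})

test_that("lineage-mode errors are inherited by descendants", {
    set.seed(4)
    ## huge error rate so every copy mutates: after 2 cycles at e=1 the
    ## chains must form the full binary-tree ancestry
    p <- amplifyPcr(1L, 2L, 1, errorRate = 0.5, insertLength = 10L,
                    errorModel = "lineage")
    expect_equal(p$poolSize, 4L)
    expect_true(all(p$chain[p$repl > 0L] > 0L))
    expect_true(all(p$chains$pos >= 0L & p$chains$pos < 10L))
    ## a molecule copied twice owns a chain whose parent is its first error
    deepest <- p$chain[which.max(p$repl)]
    seen <- 0L
    while (deepest != 0L) {
        i <- match(deepest, p$chains$id)
        deepest <- p$chains$parent[i]
        seen <- seen + 1L
    }
    expect_gte(seen, 1L)
})

test_that("zero UMI error means observed UMIs equal template UMIs", {
    cfg <- simConfig(referenceLength = 200L, nTemplates = 300L,
                     pcrCycles = 3L, umiErrorRate = 0, readLength = 100L,
                     snvTable = data.frame(pos = 100, alt = NA, freq = 0.05))
    sim <- simulateReads(cfg, seed = 5)
    r <- simReads(sim)
    expect_true(all(r$umiObs == r$umiTrue))
    expect_equal(simStats(sim)$readsWithUmiError, 0L)
})

test_that("the UMI error fraction matches the binomial closed form", {
    cfg <- simConfig(referenceLength = 120L, nTemplates = 4000L,
                     pcrCycles = 3L, readLength = 60L, seqErrorRate = 0,
                     pcrErrorRate = 0,
                     snvTable = data.frame(pos = 60, alt = NA, freq = 0.01))
    sim <- simulateReads(cfg, seed = 6)
    r <- simReads(sim)
    n <- nrow(r)
    pHit <- 1 - (1 - 0.005)^10          # >= 1 error in a 10 bp UMI
    frac <- mean(r$umiObs != r$umiTrue)
    se <- sqrt(pHit * (1 - pHit) / n)
    expect_lt(abs(frac - pHit), 3 * se)
    ## erroneous copies differ by substitution only
    diffs <- r$umiObs != r$umiTrue
    expect_true(all(nchar(r$umiObs[diffs]) == 10L))
})

test_that("zero-noise families are sequence-identical and seeded runs reproduce", {
    sim <- zero_noise_sim(n = 300L, seed = 9L)
    r <- simReads(sim)
    perTemplate <- tapply(paste(r$seq1, r$seq2),
                          r$template, function(x) length(unique(x)))
    expect_true(all(perTemplate == 1L))
    sim2 <- zero_noise_sim(n = 300L, seed = 9L)
    expect_identical(simReads(sim)$qname, simReads(sim2)$qname)
    expect_identical(simReads(sim)$seq1, simReads(sim2)$seq1)
    expect_identical(sim@reference, sim2@reference)
})

test_that("truth outputs serialize exactly (TSV plain decimals, VCF AF)", {
    cfg <- simConfig(referenceLength = 300L, nTemplates = 10000L,
                     pcrCycles = 1L, readLength = 150L)
    sim <- simulateReads(cfg, seed = 10)
    tsv <- tempfile(fileext = ".tsv"); vcf <- tempfile(fileext = ".vcf")
    writeTruth(sim, tsv, vcf)
    lines <- readLines(tsv)
    expect_equal(length(lines), 10L)              # header + 9 SNVs
    expect_false(any(grepl("e-0", lines)))        # 0.0001, never 1e-04
    tab <- read.delim(tsv, colClasses = c(freq = "character"))
    expect_setequal(tab$freq, c("0.01", "0.001", "0.0001"))
    expect_setequal(tab$carriers, c(100L, 10L, 1L))

    v <- VariantAnnotation::readVcf(vcf)
    expect_equal(nrow(v), 9L)
    expect_equal(sort(unlist(VariantAnnotation::info(v)$AF)),
                 sort(S4Vectors::mcols(simTruth(sim))$freq))
    expect_equal(IRanges::start(SummarizedExperiment::rowRanges(v)),
                 S4Vectors::mcols(simTruth(sim))$pos0 + 1L)

    ## an empty spec still yields header-only files
    cfgE <- simConfig(referenceLength = 100L, nTemplates = 50L,
                      pcrCycles = 1L, snvFreqs = numeric(0),
                      snvPerFreq = integer(0), readLength = 50L)
    simE <- simulateReads(cfgE, seed = 11)
    tsvE <- tempfile(); vcfE <- tempfile(fileext = ".vcf")
    writeTruth(simE, tsvE, vcfE)
    expect_equal(length(readLines(tsvE)), 1L)
    expect_true(all(grepl("^#", readLines(vcfE))))
})

test_that("simulated FASTQ round-trips with reverse-complemented mate 2", {
    cfg <- simConfig(referenceLength = 100L, nTemplates = 20L,
                     pcrCycles = 1L, readLength = 50L, seqErrorRate = 0,
                     pcrErrorRate = 0, umiErrorRate = 0,
                     snvFreqs = numeric(0), snvPerFreq = integer(0))
    sim <- simulateReads(cfg, seed = 12)
    f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
    writeSimulatedFastq(sim, f1, f2)
    r1 <- Biostrings::readDNAStringSet(f1, format = "fastq")
    r2 <- Biostrings::readDNAStringSet(f2, format = "fastq")
    r <- simReads(sim)
    expect_equal(as.character(r1), setNames(r$seq1, names(r1)))
    expect_equal(as.character(Biostrings::reverseComplement(r2)),
                 setNames(r$seq2, names(r2)))
    ## names end in the observed UMI, recoverable by parseUmi
    expect_equal(parseUmi(names(r1)), r$umiObs)
})
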