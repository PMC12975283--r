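test_that("majority vote picks the modal sequence, never by MAPQ", {
    v <- majorityRepresentative(c("ACGT", "ACGT", "ACGT", "ACGA"))
    expect_equal(v$dominant, "ACGT")
    expect_equal(v$nReads, 4L)
    expect_equal(v$nAgreeing, 3L)
    expect_equal(v$divergence, c("1" = 1L))

    ## count tie: lexicographically smallest sequence wins even when the
    ## other read has higher MAPQ
    v <- majorityRepresentative(c("ACGT", "ACGA"), mapq = c(60L, 10L),
                                names = c("hi", "lo"))
    expect_equal(v$dominant, "ACGA")
    expect_equal(v$repIndex, 2L)

    ## among agreeing reads, MAPQ then name breaks the record tie
    v <- majorityRepresentative(c("ACGT", "ACGT", "ACGA"),
                                mapq = c(10L, 60L, 60L),
                                names = c("a", "b", "c"))
    expect_equal(v$repIndex, 2L)
    v <- majorityRepresentative(c("ACGT", "ACGT"), mapq = c(60L, 60L),
                                names = c("b", "a"))
    expect_equal(v$repIndex, 2L)

    ## singleton
    v <- majorityRepresentative("ACGT")
    expect_equal(v$nReads, 1L)
    expect_equal(v$nAgreeing, 1L)
    expect_error(majorityRepresentative(character(0)), "non-empty")
})

test_that("two-read clusters enumerate exhaustively to the tie-break rule", {
    alphabet <- c("A", "C")
    seqs <- apply(expand.grid(alphabet, alphabet, alphabet), 1L, paste,
                  collapse = "")
    for (s1 in seqs) for (s2 in seqs) {
        v <- majorityRepresentative(c(s1, s2))
        expected <- if (s1 == s2) s1 else sort(c(s1, s2), method = "radix")[1]
        expect_equal(v$dominant, expected)
    }
})

test_that("representative sequence equals the mode of random clusters", {
    set.seed(12)
    for (trial in 1:100) {
        pool <- vapply(1:4, function(i)
            paste(sample(c("A", "C", "G"), 6, TRUE), collapse = ""),
            character(1))
        seqs <- sample(pool, sample(1:20, 1L), replace = TRUE)
        v <- majorityRepresentative(seqs)
        tab <- table(seqs)                       # counting oracle
        expect_equal(max(tab), v$nAgreeing)
        expect_true(v$dominant %in% names(tab)[tab == max(tab)])
        expect_equal(seqs[v$repIndex], v$dominant)
        expect_equal(sum(v$divergence), sum(seqs != v$dominant))
    }
})

test_that("sparse clusters are dropped unless retention is on", {
    verdicts <- data.frame(clusterId = 1:4, nReads = c(1L, 2L, 3L, 4L))
    f <- filterSparse(verdicts)
    expect_equal(f$retained, c(FALSE, FALSE, TRUE, TRUE))
    expect_equal(attr(f, "nDropped"), 2L)
    f <- filterSparse(verdicts, keepSingletons = TRUE)
    expect_true(all(f$retained))
    expect_equal(nrow(filterSparse(data.frame(nReads = integer(0)))), 0L)
    ## retention monotonicity in the threshold
    retained <- vapply(1:6, function(m)
        attr(filterSparse(verdicts, minReads = m), "nRetained"), integer(1))
    expect_true(all(diff(retained) <= 0L))
})

test_that("pair merging follows the coordinate/quality rules", {
    q30 <- function(n) strrep("?", n)
    ## [100,170) + [150,220): overlap 20, merged length 120
    s1 <- strrep("A", 70); s2 <- strrep("A", 70)
    m <- mergePair(100L, s1, q30(70), 150L, s2, q30(70))
    expect_equal(m$overlap, 20L)
    expect_equal(nchar(m$seq), 120L)
    expect_equal(m$start, 100L)

    ## disagreement: A(q30) vs C(q10) -> A with quality 20
    m <- mergePair(0L, "AA", "??", 1L, "CC", "++")
    expect_equal(m$seq, "AAC")
    expect_equal(.subset2(strsplit(m$qual, ""), 1L)[2L],
                 rawToChar(as.raw(20L + 33L)))

    ## quality tie at a disagreement keeps read 1's base
    m <- mergePair(0L, "AA", "??", 1L, "CC", "??")
    expect_equal(m$seq, "AAC")
    ## ... also when read 1 is the right-hand mate
    m <- mergePair(1L, "CC", "??", 0L, "AA", "??")
    expect_equal(m$seq, "ACC")

    ## abutting mates concatenate
    m <- mergePair(0L, strrep("G", 70), q30(70), 70L, strrep("T", 70),
                   q30(70))
    expect_equal(m$overlap, 0L)
    expect_equal(m$seq, paste0(strrep("G", 70), strrep("T", 70)))

    ## a gap beyond maxGap stays unmerged
    expect_null(mergePair(0L, "AAAA", "IIII", 10L, "CCCC", "IIII"))
    expect_false(is.null(mergePair(0L, "AAAA", "IIII", 6L, "CCCC", "IIII",
                                   maxGap = 2L)))
})

test_that("merged pairs conserve flanks and the length formula", {
    set.seed(33)
    for (trial in 1:60) {
        l1 <- sample(20:40, 1L); l2 <- sample(20:40, 1L)
        s1 <- paste(sample(c("A", "C", "G", "T"), l1, TRUE), collapse = "")
        s2 <- paste(sample(c("A", "C", "G", "T"), l2, TRUE), collapse = "")
        start2 <- sample(0:l1, 1L)               # overlap or abut
        m <- mergePair(0L, s1, strrep("I", l1), start2, s2, strrep("E", l2))
        overlap <- max(0L, min(l1, start2 + l2) - start2)
        expect_equal(nchar(m$seq), l1 + l2 - overlap)
        ## left flank bit-exact from read 1, right flank from read 2
        expect_equal(substr(m$seq, 1L, start2), substr(s1, 1L, start2))
        if (start2 + l2 > l1)
            expect_equal(substring(m$seq, l1 + 1L), substring(s2, overlap + 1L))
        ## agreeing overlap bases keep the max quality
        if (overlap > 0L) {
            bases1 <- substr(s1, start2 + 1L, start2 + overlap)
            bases2 <- substr(s2, 1L, overlap)
            agree <- strsplit(bases1, "")[[1]] == strsplit(bases2, "")[[1]]
            qm <- utf8ToInt(substr(m$qual, start2 + 1L, start2 + overlap)) - 33L
            expect_true(all(qm[agree] == max(utf8ToInt("I"), utf8ToInt("E")) - 33L))
        }
    }
})

test_that("length stratification splits groups exactly by read length", {
    st <- stratifyByLength(c(70, 70, 75, 70, 75, 70, 70))
    expect_equal(lengths(st), c("70" = 5L, "75" = 2L))
    expect_equal(st[["75"]], c(3L, 5L))
    expect_equal(stratifyByLength(rep(100, 4)), list("100" = 1:4))
    expect_equal(stratifyByLength(numeric(0)), list())
    expect_equal(stratifyByLength(data.frame(readLen = c(5, 6))),
                 list("5" = 1L, "6" = 2L))
})
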