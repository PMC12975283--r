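#' Construct a simulation configuration
#'
#' Builds a [SimConfig-class] describing an in-silico UMI benchmark: a
#' template population with SNVs planted at exact allele frequencies, UMI
#' tagging, branching-process PCR and paired-end read simulation. Defaults
#' are the benchmark conditions of the validation study (see the class
#' documentation); every parameter can be overridden.
#'
#' @param referenceLength reference length in bp (ignored when `reference`
#'   is given).
#' @param reference explicit reference sequence, or `""` to generate one.
#' @param nTemplates number of unique templates N (default 30000).
#' @param snvFreqs allele-frequency strata (default 1%, 0.1%, 0.01%).
#' @param snvPerFreq independent SNVs per stratum (default 3: nine SNVs).
#' @param snvTable optional explicit `data.frame(pos, alt, freq)` (0-based
#'   positions); overrides the stratum spec.
#' @param pcrCycles PCR cycles c (default 7).
#' @param pcrEfficiency per-cycle copy probability e (default 0.9).
#' @param pcrErrorRate per-base replication error mu (default 1e-6).
#' @param errorModel `"replication"` (per final molecule, scaled by its
#'   replication count; default) or `"lineage"` (per copy event, inherited
#'   by descendants).
#' @param umiLength UMI length L (default 10).
#' @param umiErrorRate per-base UMI sequencing error epsilon (default 0.005).
#' @param readLength read length R (default 250; 2 x 250 bp tiles the
#'   default 500 bp amplicon exactly).
#' @param seqErrorRate per-base read sequencing substitution rate (default
#'   1e-3, written as the matching Phred quality).
#' @param fragment `"amplicon"` (fragment = whole template; default) or
#'   `"normal"`.
#' @param fragmentMean,fragmentSd fragment-size model for
#'   `fragment = "normal"`, truncated to `[readLength, template length]`.
#' @param yield fraction of PCR-pool molecules sequenced (default 1).
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(referenceLength = 500L, reference = "",
                      nTemplates = 30000L,
                      snvFreqs = c(0.01, 0.001, 0.0001), snvPerFreq = 3L,
                      snvTable = data.frame(),
                      pcrCycles = 7L, pcrEfficiency = 0.9,
                      pcrErrorRate = 1e-6, errorModel = "replication",
                      umiLength = 10L, umiErrorRate = 0.005,
                      readLength = 250L, seqErrorRate = 1e-3,
                      fragment = "amplicon", fragmentMean = 300,
                      fragmentSd = 50, yield = 1) {
    new("SimConfig",
        referenceLength = as.integer(referenceLength),
        reference = toupper(reference),
        nTemplates = as.integer(nTemplates),
        snvFreqs = as.numeric(snvFreqs),
        snvPerFreq = as.integer(rep(snvPerFreq,
            length.out = length(snvFreqs))),
        snvTable = as.data.frame(snvTable),
        pcrCycles = as.integer(pcrCycles),
        pcrEfficiency = as.numeric(pcrEfficiency),
        pcrErrorRate = as.numeric(pcrErrorRate),
        errorModel = errorModel,
        umiLength = as.integer(umiLength),
        umiErrorRate = as.numeric(umiErrorRate),
        readLength = as.integer(readLength),
        seqErrorRate = as.numeric(seqErrorRate),
        fragment = fragment,
        fragmentMean = as.numeric(fragmentMean),
        fragmentSd = as.numeric(fragmentSd),
        yield = as.numeric(yield))
}

.BASES <- c("A", "C", "G", "T")

.randomReference <- function(len) {
    paste(sample(.BASES, len, replace = TRUE), collapse = "")
}

## substitute bases at (row, pos) with given alt bases; loops only over the
## maximum number of edits per row (vectorized substr<- per pass)
.applyEditsFixed <- function(seqs, row, pos, alt) {
    while (length(row)) {
        first <- !duplicated(row)
        r <- row[first]
        s <- seqs[r]
        substr(s, pos[first], pos[first]) <- alt[first]
        seqs[r] <- s
        row <- row[!first]; pos <- pos[!first]; alt <- alt[!first]
    }
    seqs
}

## draw substitutions: each edited base becomes one of the three other
## bases uniformly (an N becomes any of A/C/G/T)
.drawAlt <- function(cur) {
    ci <- match(cur, .BASES)
    shift <- sample.int(3L, length(cur), replace = TRUE)
    ai <- ((ci - 1L + shift) %% 4L) + 1L
    nIdx <- is.na(ci)
    if (any(nIdx)) ai[nIdx] <- sample.int(4L, sum(nIdx), replace = TRUE)
    .BASES[ai]
}

.applyEditsRandom <- function(seqs, row, pos) {
    if (length(row) == 0L) return(seqs)
    cur <- substr(seqs[row], pos, pos)
    .applyEditsFixed(seqs, row, pos, .drawAlt(cur))
}

#' Plant SNVs into a template population
#'
#' Assigns each planted variant to exactly `round(f * N)` carrier templates
#' — exact counts, not binomial draws, so the planted frequencies are
#' recoverable by counting. Carrier sets are sampled independently across
#' SNVs; non-carrier templates remain pure reference.
#'
#' @param reference reference sequence (character scalar).
#' @param nTemplates number of templates N.
#' @param snvFreqs,snvPerFreq frequency strata and SNVs per stratum (used
#'   when `snvTable` is empty).
#' @param snvTable optional explicit `data.frame(pos, alt, freq)`, 0-based
#'   positions. Duplicate positions or alt equal to the reference base are
#'   fatal.
#' @return a list:
#'   \item{snvs}{data.table: pos0, ref, alt, freq, carriers (count)}
#'   \item{carrierSets}{list of integer template-id vectors, one per SNV}
#'   \item{haplotypes}{character vector of N template sequences}
#' @export
plantSnvs <- function(reference, nTemplates,
                      snvFreqs = c(0.01, 0.001, 0.0001), snvPerFreq = 3L,
                      snvTable = NULL) {
    len <- nchar(reference)
    N <- as.integer(nTemplates)
    if (is.null(snvTable) || NROW(snvTable) == 0L) {
        snvPerFreq <- rep(as.integer(snvPerFreq), length.out = length(snvFreqs))
        nSnv <- sum(snvPerFreq)
        lo <- min(10L, len %/% 10L)
        interior <- seq.int(lo, len - lo - 1L)   # 0-based interior
        if (length(interior) < nSnv)
            stop("reference too short to place ", nSnv, " distinct SNVs")
        pos0 <- sort(sample(interior, nSnv))
        freq <- rep(snvFreqs, times = snvPerFreq)
        ## shuffle so neighbouring positions are not all one stratum
        freq <- sample(freq)
        ref <- substr(rep(reference, nSnv), pos0 + 1L, pos0 + 1L)
        alt <- .drawAlt(ref)
    } else {
        snvTable <- as.data.frame(snvTable)
        if (anyDuplicated(snvTable$pos))
            stop("SNV positions must be distinct")
        pos0 <- as.integer(snvTable$pos)
        if (any(pos0 < 0L | pos0 >= len))
            stop("SNV positions outside the reference")
        freq <- as.numeric(snvTable$freq)
        ref <- substr(rep(reference, length(pos0)), pos0 + 1L, pos0 + 1L)
        alt <- toupper(as.character(snvTable$alt))
        if (anyNA(alt)) alt[is.na(alt)] <- .drawAlt(ref[is.na(alt)])
        if (any(alt == ref))
            stop("alt allele equals the reference base at position(s) ",
                 paste(pos0[alt == ref], collapse = ", "))
    }
    carriers <- as.integer(round(freq * N))
    if (any(carriers < 1L))
        stop("unsatisfiable SNV spec: f * N < 0.5 leaves a variant with no ",
             "carrier (f = ", paste(freq[carriers < 1L], collapse = ", "), ")")
    carrierSets <- lapply(carriers, function(k) sample.int(N, k))
    haplotypes <- rep(reference, N)
    for (i in seq_along(pos0)) {
        idx <- carrierSets[[i]]
        s <- haplotypes[idx]
        substr(s, pos0[i] + 1L, pos0[i] + 1L) <- alt[i]
        haplotypes[idx] <- s
    }
    list(snvs = data.table(pos0 = pos0, ref = ref, alt = alt, freq = freq,
                           carriers = carriers),
         carrierSets = carrierSets,
         haplotypes = haplotypes)
}

#' Draw UMIs for a template population
#'
#' UMIs are drawn uniformly over `{A,C,G,T}^L`, independently per template.
#' Collisions (two templates sharing a UMI) are allowed but counted — they
#' model barcode collisions. By the birthday approximation the expected
#' collision count is `N^2 / (2 * 4^L)`; a warning is raised when this
#' exceeds 5% of the population, i.e. when the barcode space is clearly too
#' small (a 10 bp UMI over 30000 templates sits near 1.4% and stays quiet;
#' a 1 bp UMI over 100 templates does not).
#'
#' @param n number of templates.
#' @param umiLength UMI length L.
#' @return character vector of UMIs with attribute `collisions` (count of
#'   templates whose UMI duplicates an earlier one).
#' @export
tagUmis <- function(n, umiLength) {
    expected <- n^2 / (2 * 4^umiLength)
    if (expected > 0.05 * n)
        warning(sprintf(
            "UMI space 4^%d is small for %d templates (~%.1f expected collisions)",
            umiLength, n, expected))
    m <- matrix(sample(.BASES, n * umiLength, replace = TRUE), nrow = n)
    umis <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    structure(umis, collisions = sum(duplicated(umis)))
}

#' Branching-process PCR amplification
#'
#' Each cycle, every molecule in the pool is copied with probability
#' `efficiency`; the expected pool size after c cycles is
#' `n * (1 + efficiency)^c`. Replication errors occur at `errorRate` per
#' base per copy event. Under the default `"replication"` error model each
#' final molecule's ancestry replication count is tracked and its errors are
#' drawn at sequencing time from `Binomial(insert length, count * errorRate)`;
#' under `"lineage"`, errors are drawn at each copy event and inherited by
#' all descendants of the erroneous copy.
#'
#' @param templates number of input molecules (scalar) or an integer vector
#'   of template ids (one entry per molecule).
#' @param cycles number of PCR cycles (>= 0).
#' @param efficiency per-cycle copy probability in (0, 1].
#' @param errorRate per-base replication error probability.
#' @param insertLength insert length per template (scalar or vector indexed
#'   by template id); needed when `errorRate > 0` and
#'   `errorModel = "lineage"`.
#' @param errorModel `"replication"` or `"lineage"`.
#' @return a list:
#'   \item{template}{template id per pool molecule}
#'   \item{repl}{replication events in each molecule's ancestry}
#'   \item{chain}{mutation-chain id per molecule (0 = none; lineage model)}
#'   \item{chains}{data.table(id, parent, pos, shift) of lineage mutations,
#'     positions 0-based within the insert}
#'   \item{poolSize}{total number of molecules}
#' @export
amplifyPcr <- function(templates, cycles, efficiency, errorRate = 0,
                       insertLength = 0L, errorModel = "replication") {
    if (length(templates) == 1L && is.numeric(templates) &&
        templates == round(templates) && is.null(names(templates)))
        templates <- seq_len(templates)
    tmpl <- as.integer(templates)
    n0 <- length(tmpl)
    repl <- integer(n0)
    chain <- integer(n0)
    lineage <- identical(errorModel, "lineage") && errorRate > 0
    chains <- list(id = integer(0), parent = integer(0), pos = integer(0),
                   shift = integer(0))
    nextChain <- 0L
    insLen <- as.integer(insertLength)
    for (cyc in seq_len(cycles)) {
        nPool <- length(tmpl)
        copied <- which(rbinom(nPool, 1L, efficiency) == 1L)
        if (length(copied) == 0L) next
        newT <- tmpl[copied]
        newR <- repl[copied] + 1L
        newC <- chain[copied]
        if (lineage) {
            li <- if (length(insLen) == 1L) rep(insLen, length(copied))
                  else insLen[newT]
            k <- rbinom(length(copied), li, errorRate)
            hit <- which(k > 0L)
            for (j in hit) {
                for (b in seq_len(k[j])) {
                    nextChain <- nextChain + 1L
                    chains$id <- c(chains$id, nextChain)
                    chains$parent <- c(chains$parent, newC[j])
                    chains$pos <- c(chains$pos, sample.int(li[j], 1L) - 1L)
                    chains$shift <- c(chains$shift, sample.int(3L, 1L))
                    newC[j] <- nextChain
                }
            }
        }
        tmpl <- c(tmpl, newT)
        repl <- c(repl, newR)
        chain <- c(chain, newC)
    }
    list(template = tmpl, repl = repl, chain = chain,
         chains = data.table(id = chains$id, parent = chains$parent,
                             pos = chains$pos, shift = chains$shift),
         poolSize = length(tmpl))
}

## resolve a lineage mutation chain to its (pos, shift) edits
.decodeChain <- function(chains, id) {
    pos <- integer(0); shift <- integer(0)
    while (id != 0L) {
        i <- match(id, chains$id)
        pos <- c(pos, chains$pos[i])
        shift <- c(shift, chains$shift[i])
        id <- chains$parent[i]
    }
    list(pos = pos, shift = shift)
}

.phredOf <- function(p) if (p <= 0) 40L else as.integer(round(-10 * log10(p)))

#' Simulate a UMI-tagged amplicon benchmark
#'
#' Runs the full generative model: reference (given or random), template
#' population with planted SNVs ([plantSnvs()]), per-template fragments,
#' UMI tagging ([tagUmis()]), branching PCR ([amplifyPcr()]) and paired-end
#' read simulation with per-base sequencing errors and independent per-base
#' UMI sequencing errors. Fragmentation precedes tagging and amplification,
#' so all PCR copies of one template share its fragment coordinates — the
#' property that makes coordinate-wise UMI grouping meaningful.
#'
#' Read names encode the template and molecule id for truth tracking and
#' carry the \emph{observed} (error-bearing) UMI as the last
#' underscore-separated token.
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @param seed integer seed; every random draw in the simulation flows from
#'   it, so equal seeds give byte-identical output.
#' @return a [UmiSimulation-class].
#' @export
simulateReads <- function(config, seed = NULL) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    if (!is.null(seed)) set.seed(seed)
    reference <- if (nzchar(config@reference)) config@reference
                 else .randomReference(config@referenceLength)
    len <- nchar(reference)
    N <- config@nTemplates

    planted <- plantSnvs(reference, N,
                         snvFreqs = config@snvFreqs,
                         snvPerFreq = config@snvPerFreq,
                         snvTable = if (nrow(config@snvTable)) config@snvTable)

    ## per-template fragments (before tagging and amplification)
    R <- config@readLength
    if (config@fragment == "amplicon") {
        fs <- rep(0L, N)
        fl <- rep(len, N)
    } else {
        fl <- as.integer(round(rnorm(N, config@fragmentMean, config@fragmentSd)))
        fl <- pmin(pmax(fl, R), len)
        fs <- as.integer(floor(runif(N, 0, len - fl + 1)))
    }

    umis <- tagUmis(N, config@umiLength)
    nCollisions <- attr(umis, "collisions")

    pool <- amplifyPcr(N, config@pcrCycles, config@pcrEfficiency,
                       errorRate = config@pcrErrorRate,
                       insertLength = fl, errorModel = config@errorModel)
    keep <- seq_len(pool$poolSize)
    if (config@yield < 1)
        keep <- sort(sample(keep, max(1L, round(config@yield * pool$poolSize))))
    tmpl <- pool$template[keep]
    repl <- pool$repl[keep]
    chain <- pool$chain[keep]
    nPool <- length(tmpl)

    ## aligned-orientation base reads from the template haplotypes
    mfs <- fs[tmpl]; mfl <- fl[tmpl]
    r1len <- pmin(R, mfl)
    r2len <- pmin(R, mfl)
    start1 <- mfs
    start2 <- mfs + mfl - r2len
    seq1 <- substr(planted$haplotypes[tmpl], mfs + 1L, mfs + r1len)
    seq2 <- substr(planted$haplotypes[tmpl], start2 + 1L, start2 + r2len)

    ## PCR replication errors
    if (config@pcrErrorRate > 0) {
        if (config@errorModel == "replication") {
            pErr <- pmin(1, repl * config@pcrErrorRate)
            k <- rbinom(nPool, mfl, pErr)
            hit <- which(k > 0L)
            row <- rep(hit, k[hit])
            fpos <- floor(runif(length(row)) * mfl[row])   # 0-based in fragment
        } else {
            hit <- which(chain > 0L)
            row <- integer(0); fpos <- integer(0)
            for (i in hit) {
                dec <- .decodeChain(pool$chains, chain[i])
                row <- c(row, rep(i, length(dec$pos)))
                fpos <- c(fpos, dec$pos)
            }
        }
        if (length(row)) {
            ## errors landing between the mate windows are unobserved
            obs <- fpos < r1len[row] | fpos >= (mfl[row] - r2len[row])
            row <- row[obs]; fpos <- fpos[obs]
        }
        if (length(row)) {
            ## read the current base from whichever mate covers the site,
            ## draw the substitution once, apply to both mates if shared
            in1 <- fpos < r1len[row]
            in2 <- fpos >= (mfl[row] - r2len[row])
            curPos1 <- fpos + 1L
            cur <- ifelse(in1, substr(seq1[row], curPos1, curPos1),
                          substr(seq2[row], fpos - (mfl[row] - r2len[row]) + 1L,
                                 fpos - (mfl[row] - r2len[row]) + 1L))
            alt <- .drawAlt(cur)
            i1 <- which(in1)
            seq1 <- .applyEditsFixed(seq1, row[i1], fpos[i1] + 1L, alt[i1])
            i2 <- which(in2)
            p2 <- fpos[i2] - (mfl[row[i2]] - r2len[row[i2]]) + 1L
            seq2 <- .applyEditsFixed(seq2, row[i2], p2, alt[i2])
        }
    }

    ## sequencing errors, independent per read
    if (config@seqErrorRate > 0) {
        for (mate in 1:2) {
            rl <- if (mate == 1L) r1len else r2len
            k <- rbinom(nPool, rl, config@seqErrorRate)
            hit <- which(k > 0L)
            row <- rep(hit, k[hit])
            p <- ceiling(runif(length(row)) * rl[row])
            if (mate == 1L) seq1 <- .applyEditsRandom(seq1, row, p)
            else seq2 <- .applyEditsRandom(seq2, row, p)
        }
    }

    ## observed UMI: one copy per read pair, per-base substitution at epsilon
    umiObs <- umis[tmpl]
    nUmiErrReads <- 0L
    if (config@umiErrorRate > 0) {
        k <- rbinom(nPool, config@umiLength, config@umiErrorRate)
        hit <- which(k > 0L)
        nUmiErrReads <- length(hit)
        row <- rep(hit, k[hit])
        p <- ceiling(runif(length(row)) * config@umiLength)
        umiObs <- .applyEditsRandom(umiObs, row, p)
    }

    q <- .phredOf(config@seqErrorRate)
    qual1 <- strrep(intToUtf8(q + 33L), r1len)
    qual2 <- strrep(intToUtf8(q + 33L), r2len)

    reads <- data.table(
        template = tmpl, molecule = keep, repl = repl,
        umiTrue = umis[tmpl], umiObs = umiObs,
        start1 = start1, seq1 = seq1, qual1 = qual1,
        start2 = start2, seq2 = seq2, qual2 = qual2,
        qname = sprintf("T%d.M%d_%s", tmpl, keep, umiObs))

    truth <- GenomicRanges::GRanges(
        seqnames = rep("amplicon", nrow(planted$snvs)),
        ranges = IRanges::IRanges(start = planted$snvs$pos0 + 1L, width = 1L),
        ref = planted$snvs$ref, alt = planted$snvs$alt,
        freq = planted$snvs$freq, carriers = planted$snvs$carriers,
        pos0 = planted$snvs$pos0)

    templates <- data.table(id = seq_len(N), umi = as.character(umis),
                            fragStart = fs, fragLen = fl,
                            haplotype = planted$haplotypes)

    new("UmiSimulation",
        config = config, reference = reference,
        templates = as.data.frame(templates),
        truth = truth, reads = reads,
        stats = list(poolSize = pool$poolSize, readPairs = nPool,
                     umiCollisions = nCollisions,
                     readsWithUmiError = nUmiErrReads,
                     carrierSets = planted$carrierSets))
}

#' @rdname UmiSimulation-accessors
#' @param x a `UmiSimulation`.
#' @export
setMethod("simTruth", "UmiSimulation", function(x) x@truth)

#' @rdname UmiSimulation-accessors
#' @export
setMethod("simReads", "UmiSimulation", function(x) x@reads)

#' @rdname UmiSimulation-accessors
#' @export
setMethod("simTemplates", "UmiSimulation", function(x) x@templates)

#' @rdname UmiSimulation-accessors
#' @export
setMethod("simStats", "UmiSimulation", function(x) x@stats)

setMethod("show", "UmiSimulation", function(object) {
    cat("UmiSimulation:", nrow(object@templates), "templates,",
        object@stats$readPairs, "read pairs,",
        length(object@truth), "planted SNVs\n")
    cat("  reference:", nchar(object@reference), "bp;",
        "UMI collisions:", object@stats$umiCollisions, ";",
        "pairs with UMI errors:", object@stats$readsWithUmiError, "\n")
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nTemplates, "templates on",
        if (nzchar(object@reference)) nchar(object@reference)
        else object@referenceLength, "bp reference\n")
    cat(sprintf("  PCR: %d cycles, efficiency %.2f, error %g (%s model)\n",
                object@pcrCycles, object@pcrEfficiency, object@pcrErrorRate,
                object@errorModel))
    cat(sprintf("  UMI: %d bp, sequencing error %g\n",
                object@umiLength, object@umiErrorRate))
    cat(sprintf("  reads: 2 x %d bp, base error %g, fragment model '%s'\n",
                object@readLength, object@seqErrorRate, object@fragment))
})
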