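# Independent reference implementations used to freeze expected values.
# These deliberately share no code with the package: naive data structures,
# explicit loops, fixed-point iteration instead of BFS.

oracle_hamming <- function(a, b) {
    va <- strsplit(a, "")[[1]]
    vb <- strsplit(b, "")[[1]]
    stopifnot(length(va) == length(vb))
    sum(va != vb | va == "N" | vb == "N")
}

# all indexed strings within distance k of q, by linear scan
oracle_neighbors <- function(umis, q, k) {
    umis[vapply(umis, oracle_hamming, integer(1), a = q) <= k]
}

# UMI clustering by exhaustive merge-rule evaluation. Roots are taken in
# descending-count order (ties lexicographic, C locale); directional
# clusters are the least fixed point of "absorb any unassigned v within
# maxEdits of a member u with cnt[u] >= mult*cnt[v] - 1"; acyclic restricts
# to the root. Returns a canonical partition: a sorted list of sorted
# member-UMI vectors.
oracle_cluster <- function(counts, method = "directional", maxEdits = 1,
                           mult = 2) {
    umis <- names(counts)
    cnt <- as.integer(counts)
    ord <- order(-cnt, rank(umis))   # rank() on ACGT strings is locale-safe
    umis <- umis[ord]
    cnt <- cnt[ord]
    n <- length(umis)
    D <- matrix(0L, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        D[i, j] <- oracle_hamming(umis[i], umis[j])
    assigned <- integer(n)
    cid <- 0L
    for (r in seq_len(n)) {
        if (assigned[r] > 0L) next
        cid <- cid + 1L
        assigned[r] <- cid
        if (method == "raw") next
        if (method == "acyclic") {
            for (v in seq_len(n)) {
                if (assigned[v] == 0L && D[r, v] <= maxEdits &&
                    cnt[r] >= mult * cnt[v] - 1) assigned[v] <- cid
            }
        } else {
            repeat {
                members <- which(assigned == cid)
                grew <- FALSE
                for (v in seq_len(n)) {
                    if (assigned[v] > 0L) next
                    ok <- any(D[members, v] <= maxEdits &
                              cnt[members] >= mult * cnt[v] - 1)
                    if (ok) { assigned[v] <- cid; grew <- TRUE }
                }
                if (!grew) break
            }
        }
    }
    canonical_partition(split(umis, assigned))
}

canonical_partition <- function(parts) {
    parts <- lapply(parts, function(p) sort(unname(p), method = "radix"))
    keys <- vapply(parts, paste, character(1), collapse = ",")
    unname(parts[order(keys, method = "radix")])
}

partition_of <- function(clustering) {
    canonical_partition(split(clustering@umi, clustering@membership))
}

# random UmiCounts instance; small alphabets force near-neighbor structure
random_umi_counts <- function(maxUmis = 12L, lenRange = 6:10) {
    len <- sample(lenRange, 1L)
    alpha <- sample(list(c("A", "C"), c("A", "C", "G"),
                         c("A", "C", "G", "T")), 1L)[[1]]
    k <- sample.int(maxUmis, 1L)
    umis <- unique(vapply(seq_len(k), function(i)
        paste(sample(alpha, len, replace = TRUE), collapse = ""),
        character(1)))
    counts <- sample.int(50L, length(umis), replace = TRUE)
    setNames(counts, umis)
}
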