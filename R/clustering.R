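#' Hamming distance between equal-length sequences
#'
#' Vectorized substitution-count distance. An `N` in either sequence counts
#' as a mismatch at that position, including against another `N`: ambiguous
#' barcode bases never silently match, so ambiguous UMIs are not merged on
#' the strength of their unreadable positions.
#'
#' @param a,b character vectors of equal-length strings; either argument may
#'   have length 1 and is recycled.
#' @param allowUnequal if `TRUE`, pairs of unequal length yield `NA` instead
#'   of an error (used when binning read-to-consensus divergence, where
#'   unequal lengths fall into an "other" bucket).
#' @return integer vector of mismatch counts.
#' @examples
#' hammingDistance("ACGT", "ACGA")  # 1
#' hammingDistance("NNNN", "NNNN")  # 4
#' @export
hammingDistance <- function(a, b, allowUnequal = FALSE) {
    d <- hamming_cpp(as.character(a), as.character(b))
    if (any(d < 0L)) {
        if (!allowUnequal)
            stop("sequences must have equal length; stratify by length first")
        d[d < 0L] <- NA_integer_
    }
    d
}

#' Build a BK-tree index over UMI strings
#'
#' A Burkhard-Keller metric tree under Hamming distance. Queries prune
#' subtrees using the triangle inequality, so neighbor search within a small
#' edit radius touches only a fraction of the indexed strings.
#'
#' @param umis character vector of equal-length strings.
#' @return a [BKTree-class] object.
#' @seealso [bkQuery()]
#' @export
bkTree <- function(umis) {
    umis <- as.character(umis)
    new("BKTree", ptr = bktree_build_cpp(umis), umis = umis)
}

.bktreePtr <- function(tree) {
    ## external pointers do not survive serialization; rebuild transparently
    if (is.null(tree@ptr) || identical(tree@ptr, new("externalptr")) ||
        bktree_size_cpp(tree@ptr) != length(tree@umis))
        tree@ptr <- bktree_build_cpp(tree@umis)
    tree@ptr
}

#' Query a BK-tree for all strings within a Hamming radius
#'
#' @param tree a [BKTree-class] built by [bkTree()].
#' @param query a single string of the indexed length.
#' @param maxDist maximum Hamming distance (inclusive).
#' @param value if `TRUE` (default) return the matching strings; otherwise
#'   their 1-based indices into the indexed vector.
#' @return exactly the indexed strings `v` with `hammingDistance(query, v) <=
#'   maxDist`, in indexed order.
#' @export
bkQuery <- function(tree, query, maxDist = 1L, value = TRUE) {
    stopifnot(is(tree, "BKTree"), length(query) == 1L)
    idx <- bktree_query_cpp(.bktreePtr(tree), as.character(query),
                            as.integer(maxDist))
    if (value) tree@umis[idx] else idx
}

#' @describeIn bkTree number of indexed strings.
#' @param object,x a `BKTree`.
#' @export
setMethod("length", "BKTree", function(x) length(x@umis))

setMethod("show", "BKTree", function(object) {
    cat("BKTree with", length(object@umis), "strings of length",
        if (length(object@umis)) nchar(object@umis[1]) else 0, "\n")
})

#' Cluster UMIs within a position group
#'
#' Corrects UMI synthesis/sequencing errors by partitioning the UMIs observed
#' at one genomic grouping key into clusters presumed to derive from single
#' template molecules.
#'
#' Three modes are supported:
#' \describe{
#'   \item{directional}{Iterative abundance-aware merging. UMIs are processed
#'     in descending count order (ties lexicographic). Starting from an
#'     unassigned root, any unassigned UMI `v` within `maxEdits` of any
#'     current cluster member `u` is absorbed when
#'     `count(u) >= thresholdMultiplier * count(v) - 1`, and the expansion
#'     continues transitively until closure.}
#'   \item{acyclic}{The non-iterative restriction: only UMIs directly
#'     adjacent to the root (within `maxEdits` of it, passing the threshold
#'     against the root's count) are absorbed. Prevents over-collapsing with
#'     long UMIs or few PCR cycles.}
#'   \item{raw}{No correction; every distinct UMI string is its own cluster.}
#' }
#'
#' The partition is deterministic: it depends only on the count mapping, not
#' on the order of `counts`.
#'
#' @param counts named integer vector (names = UMI strings, values = read
#'   counts >= 1), or a table coercible to one. All UMIs must share one
#'   length; stratify unequal lengths before clustering.
#' @param method "directional" (default), "acyclic" or "raw".
#' @param maxEdits maximum Hamming distance merged (default 1).
#' @param thresholdMultiplier abundance-rule multiplier (default 2, i.e.
#'   `count(parent) >= 2 * count(child) - 1`).
#' @return a [UmiClustering-class].
#' @examples
#' clusterUmis(c(AAAA = 10, AAAT = 1))                      # one cluster
#' clusterUmis(c(AAAA = 5, AAAT = 5))                       # two: 5 < 2*5-1
#' clusterUmis(c(AAAA = 100, AAAT = 4, AATT = 1))           # chain, one cluster
#' clusterUmis(c(AAAA = 100, AAAT = 4, AATT = 1), "acyclic") # two clusters
#' @export
clusterUmis <- function(counts,
                        method = c("directional", "acyclic", "raw"),
                        maxEdits = 1L, thresholdMultiplier = 2) {
    method <- match.arg(method)
    if (is.table(counts)) counts <- setNames(as.integer(counts), names(counts))
    if (is.null(names(counts)) || length(counts) == 0L)
        stop("counts must be a non-empty named vector (names are UMIs)")
    umis <- names(counts)
    cnt <- as.integer(counts)
    if (any(cnt < 1L)) stop("all counts must be >= 1")
    if (length(unique(nchar(umis))) > 1L)
        stop("all UMIs must have equal length; stratify by length first")
    if (anyDuplicated(umis)) stop("duplicate UMI strings in counts")

    ## canonical processing order: descending count, ties lexicographic
    ## (C locale, so the order is platform-independent)
    o <- order(-cnt, method_radix_order(umis))
    umis <- umis[o]
    cnt <- cnt[o]

    membership <- switch(method,
        raw = seq_along(umis),
        directional = cluster_umis_cpp(umis, cnt, as.integer(maxEdits),
                                       as.numeric(thresholdMultiplier), 0L),
        acyclic = cluster_umis_cpp(umis, cnt, as.integer(maxEdits),
                                   as.numeric(thresholdMultiplier), 1L)
    )
    new("UmiClustering",
        umi = umis, count = cnt, membership = as.integer(membership),
        method = method, maxEdits = as.integer(maxEdits),
        thresholdMultiplier = as.numeric(thresholdMultiplier))
}

## C-locale lexicographic rank, independent of the session collation
method_radix_order <- function(x) {
    xtfrm(factor(x, levels = sort(unique(x), method = "radix")))
}

#' Accessors for [UmiClustering-class]
#'
#' `nClusters` gives the number of clusters, `clusterSizes` the total read
#' count per cluster, `clusterRoots` the root (highest-count) UMI per
#' cluster, `clusterMembership` a named integer vector mapping each UMI to
#' its cluster id, and `totalReads` the conserved total read count.
#'
#' @param x a `UmiClustering`.
#' @return see description.
#' @name UmiClustering-accessors
NULL

#' @rdname UmiClustering-accessors
#' @export
setMethod("nClusters", "UmiClustering", function(x) {
    if (length(x@membership) == 0L) 0L else max(x@membership)
})

#' @rdname UmiClustering-accessors
#' @export
setMethod("clusterSizes", "UmiClustering", function(x) {
    as.integer(rowsum(x@count, x@membership)[, 1L])
})

#' @rdname UmiClustering-accessors
#' @export
setMethod("clusterRoots", "UmiClustering", function(x) {
    x@umi[!duplicated(x@membership)]
})

#' @rdname UmiClustering-accessors
#' @export
setMethod("clusterMembership", "UmiClustering", function(x) {
    setNames(x@membership, x@umi)
})

#' @rdname UmiClustering-accessors
#' @export
setMethod("totalReads", "UmiClustering", function(x) sum(x@count))

setMethod("show", "UmiClustering", function(object) {
    cat("UmiClustering (", object@method, " mode): ",
        length(object@umi), " UMIs in ", nClusters(object), " clusters, ",
        totalReads(object), " reads\n", sep = "")
    if (object@method != "raw")
        cat("  maxEdits =", object@maxEdits,
            ", threshold multiplier =", object@thresholdMultiplier, "\n")
})
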