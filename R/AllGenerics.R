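#' @rdname UmiClustering-accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname UmiClustering-accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname UmiClustering-accessors
#' @export
setGeneric("clusterMembership", function(x) standardGeneric("clusterMembership"))

#' @rdname UmiClustering-accessors
#' @export
setGeneric("clusterRoots", function(x) standardGeneric("clusterRoots"))

#' @rdname UmiClustering-accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname DedupResult-accessors
#' @export
setGeneric("dedupStats", function(x) standardGeneric("dedupStats"))

#' @rdname DedupResult-accessors
#' @export
setGeneric("clusterVerdicts", function(x) standardGeneric("clusterVerdicts"))

#' @rdname DedupResult-accessors
#' @export
setGeneric("dedupBamPath", function(x) standardGeneric("dedupBamPath"))

#' @rdname EvalMetrics-accessors
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))

#' @rdname UmiSimulation-accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @rdname UmiSimulation-accessors
#' @export
setGeneric("simReads", function(x) standardGeneric("simReads"))

#' @rdname UmiSimulation-accessors
#' @export
setGeneric("simTemplates", function(x) standardGeneric("simTemplates"))

#' @rdname UmiSimulation-accessors
#' @export
setGeneric("simStats", function(x) standardGeneric("simStats"))
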