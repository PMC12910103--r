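#' Accessor generics
#'
#' Accessors for the classes in this package. `svMatrix()` returns the Sv
#' matrix (dB) of an [Echogram] or [IntegrationGrid]; `depthAxis()` the depth
#' bin centres (m); `pingTimes()`/`pingPositions()` the per-column time and
#' lat/lon; `frequencyKHz()` the acoustic frequency; `nSamples()` the per-cell
#' sample counts of a grid; `cellDistances()` the cumulative along-track
#' distance (nmi) of grid columns.
#'
#' @param x an object.
#' @return the corresponding component.
#' @name accessors
#' @aliases svMatrix depthAxis pingTimes pingPositions frequencyKHz nSamples
#'   cellDistances
NULL

#' @rdname accessors
#' @export
setGeneric("svMatrix", function(x) standardGeneric("svMatrix"))
#' @rdname accessors
#' @export
setGeneric("depthAxis", function(x) standardGeneric("depthAxis"))
#' @rdname accessors
#' @export
setGeneric("pingTimes", function(x) standardGeneric("pingTimes"))
#' @rdname accessors
#' @export
setGeneric("pingPositions", function(x) standardGeneric("pingPositions"))
#' @rdname accessors
#' @export
setGeneric("frequencyKHz", function(x) standardGeneric("frequencyKHz"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("cellDistances", function(x) standardGeneric("cellDistances"))

#' Clustering result accessors
#'
#' `selectedK()` returns the silhouette-selected number of clusters,
#' `clusterLabels()` the hard assignments, `silhouetteByK()` the mean
#' silhouette width per candidate k, and `clusterSummaries()` the per-cluster
#' five-number summaries of the raw descriptors.
#'
#' @param x a [SeascapeClassification].
#' @name cluster-accessors
#' @aliases selectedK clusterLabels silhouetteByK clusterSummaries
NULL

#' @rdname cluster-accessors
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))
#' @rdname cluster-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname cluster-accessors
#' @export
setGeneric("silhouetteByK", function(x) standardGeneric("silhouetteByK"))
#' @rdname cluster-accessors
#' @export
setGeneric("clusterSummaries", function(x) standardGeneric("clusterSummaries"))

#' GAM result accessors
#'
#' `devianceExplained()` returns the percent deviance explained and
#' `termTable()` the per-term estimates/EDFs and p-values of a fitted
#' environmental driver model.
#'
#' @param x a [GAMResult].
#' @name gam-accessors
#' @aliases devianceExplained termTable
NULL

#' @rdname gam-accessors
#' @export
setGeneric("devianceExplained", function(x) standardGeneric("devianceExplained"))
#' @rdname gam-accessors
#' @export
setGeneric("termTable", function(x) standardGeneric("termTable"))
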