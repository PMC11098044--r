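# Generics and accessors. Slots are never reached into by user code; these
# are the supported surface.

#' Number of nodes (regions)
#' @param x a BrainGraph, TemplateNetwork, RegionalTimeSeries or
#'   CorrelationMatrix.
#' @return integer count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Number of volumes (time points)
#' @param x a RegionalTimeSeries.
#' @return integer count.
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' Region labels
#' @param x an object carrying a region ordering.
#' @return character vector.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' Sampling interval (seconds)
#' @param x a RegionalTimeSeries.
#' @return positive scalar.
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))

#' Metric values as a named numeric vector
#' @param x a NodalMetricProfile or ReferenceProfile.
#' @return numeric vector.
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' Metric name
#' @param x a NodalMetricProfile, ReferenceProfile or HDIEstimate.
#' @return character scalar.
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' The hub disruption index (regression slope)
#' @param x an HDIEstimate.
#' @return numeric scalar.
#' @export
setGeneric("hdi", function(x) standardGeneric("hdi"))

#' Underlying igraph object
#' @param x a BrainGraph or TemplateNetwork.
#' @return an igraph object.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Edge count
#' @param x a BrainGraph or TemplateNetwork.
#' @return integer count.
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' Planted hub indices of a template network
#' @param x a TemplateNetwork.
#' @return integer vector.
#' @export
setGeneric("hubIds", function(x) standardGeneric("hubIds"))

#' @describeIn nNodes regions of a time series
#' @export
setMethod("nNodes", "RegionalTimeSeries", function(x) ncol(x@data))

#' @describeIn nNodes regions of a correlation matrix
#' @export
setMethod("nNodes", "CorrelationMatrix", function(x) nrow(x@matrix))

#' @describeIn nNodes nodes of a brain graph
#' @export
setMethod("nNodes", "BrainGraph", function(x) igraph::vcount(x@graph))

#' @describeIn nNodes nodes of a template network
#' @export
setMethod("nNodes", "TemplateNetwork", function(x) igraph::vcount(x@graph))

#' @describeIn nVolumes volumes of a time series
#' @export
setMethod("nVolumes", "RegionalTimeSeries", function(x) nrow(x@data))

#' @describeIn regionLabels labels of a time series
#' @export
setMethod("regionLabels", "RegionalTimeSeries", function(x) x@regionLabels)

#' @describeIn regionLabels labels of a correlation matrix
#' @export
setMethod("regionLabels", "CorrelationMatrix", function(x) {
  rownames(x@matrix)
})

#' @describeIn samplingInterval repetition time of a series
#' @export
setMethod(
  "samplingInterval", "RegionalTimeSeries",
  function(x) x@samplingInterval
)

#' @describeIn metricValues values of an individual profile
#' @export
setMethod("metricValues", "NodalMetricProfile", function(x) x@values)

#' @describeIn metricValues values of a reference profile
#' @export
setMethod("metricValues", "ReferenceProfile", function(x) x@values)

#' @describeIn metricName of an individual profile
#' @export
setMethod("metricName", "NodalMetricProfile", function(x) x@metric)

#' @describeIn metricName of a reference profile
#' @export
setMethod("metricName", "ReferenceProfile", function(x) x@metric)

#' @describeIn metricName of an HDI estimate
#' @export
setMethod("metricName", "HDIEstimate", function(x) x@metric)

#' @describeIn hdi slope of the nodal-difference regression
#' @export
setMethod("hdi", "HDIEstimate", function(x) x@slope)

#' @describeIn asIgraph graph of a BrainGraph
#' @export
setMethod("asIgraph", "BrainGraph", function(x) x@graph)

#' @describeIn asIgraph graph of a template network
#' @export
setMethod("asIgraph", "TemplateNetwork", function(x) x@graph)

#' @describeIn edgeCount edges of a brain graph
#' @export
setMethod("edgeCount", "BrainGraph", function(x) igraph::ecount(x@graph))

#' @describeIn edgeCount edges of a template network
#' @export
setMethod("edgeCount", "TemplateNetwork", function(x) igraph::ecount(x@graph))

#' @describeIn hubIds planted hubs
#' @export
setMethod("hubIds", "TemplateNetwork", function(x) x@hubIds)

#' Correlation matrix as a plain numeric matrix
#' @param x a CorrelationMatrix.
#' @return numeric matrix with dimnames.
#' @export
corMatrix <- function(x) {
  stopifnot(is(x, "CorrelationMatrix"))
  x@matrix
}

#' Time-series data as a plain numeric matrix
#' @param x a RegionalTimeSeries.
#' @return volumes-by-regions matrix.
#' @export
tsMatrix <- function(x) {
  stopifnot(is(x, "RegionalTimeSeries"))
  x@data
}

setMethod("show", "RegionalTimeSeries", function(object) {
  cat(
    "RegionalTimeSeries:", nrow(object@data), "volumes x",
    ncol(object@data), "regions, TR =", object@samplingInterval, "s\n"
  )
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(
    "CorrelationMatrix:", nrow(object@matrix), "regions, wavelet scale",
    object@scale, "( n_effective =", object@nEffective, ")\n"
  )
})

setMethod("show", "BrainGraph", function(object) {
  cat(
    "BrainGraph:", igraph::vcount(object@graph), "nodes,",
    igraph::ecount(object@graph), "edges, cost =",
    signif(object@cost, 4), "\n"
  )
})

setMethod("show", "TemplateNetwork", function(object) {
  cat(
    "TemplateNetwork:", igraph::vcount(object@graph), "nodes,",
    igraph::ecount(object@graph), "edges,", length(object@hubIds),
    "planted hubs\n"
  )
})

setMethod("show", "NodalMetricProfile", function(object) {
  cat(
    "NodalMetricProfile:", object@metric, "over", length(object@values),
    "nodes (range", signif(min(object@values), 4), "-",
    signif(max(object@values), 4), ")\n"
  )
})

setMethod("show", "HDIEstimate", function(object) {
  cat(
    "HDIEstimate:", object@metric, " HDI =", signif(object@slope, 4),
    " (intercept", signif(object@intercept, 4), ", R^2 =",
    signif(object@r2, 3), ")\n"
  )
})

setMethod("show", "MixedModelFit", function(object) {
  cat("MixedModelFit (REML, cluster bootstrap n =", object@nBoot, ")\n")
  print(object@coefficients, row.names = FALSE)
})
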