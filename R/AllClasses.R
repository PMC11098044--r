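setOldClass("igraph")

#' Regional BOLD time series
#'
#' Volumes-by-regions signal matrix with region labels and the sampling
#' interval (repetition time) in seconds. The entry object of the pipeline:
#' quality control, nuisance regression and wavelet correlation all operate
#' on it.
#'
#' @slot data numeric matrix, volumes in rows, regions in columns.
#' @slot regionLabels character vector of region names, one per column.
#' @slot samplingInterval positive scalar, seconds between volumes.
#' @export
setClass("RegionalTimeSeries",
  representation(
    data = "matrix",
    regionLabels = "character",
    samplingInterval = "numeric"
  )
)

setValidity("RegionalTimeSeries", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (ncol(object@data) != length(object@regionLabels)) {
    msg <- c(msg, "region count must match number of labels")
  }
  if (length(object@samplingInterval) != 1 || is.na(object@samplingInterval) ||
    object@samplingInterval <= 0) {
    msg <- c(msg, "samplingInterval must be a positive scalar")
  }
  if (length(msg)) msg else TRUE
})

#' Scale-wise wavelet correlation matrix
#'
#' Symmetric regions-by-regions Pearson correlation matrix of MODWT detail
#' coefficients at one dyadic scale. Regions whose series were entirely
#' missing carry NA rows/columns and are handled downstream by the
#' single-edge attachment rule of [mstBackbone()].
#'
#' @slot matrix numeric correlation matrix with region labels as dimnames.
#' @slot scale integer wavelet level the correlations were estimated at.
#' @slot nEffective number of non-boundary coefficients used per series.
#' @export
setClass("CorrelationMatrix",
  representation(
    matrix = "matrix",
    scale = "integer",
    nEffective = "integer"
  )
)

setValidity("CorrelationMatrix", function(object) {
  m <- object@matrix
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  ok <- !is.na(m)
  if (any(abs(m[ok]) > 1 + 1e-8)) msg <- c(msg, "entries must lie in [-1, 1]")
  if (!isTRUE(all.equal(m[ok], t(m)[ok], tolerance = 1e-8))) {
    msg <- c(msg, "matrix must be symmetric")
  }
  dg <- diag(m)
  if (any(!is.na(dg) & abs(dg - 1) > 1e-8)) msg <- c(msg, "diagonal must be 1")
  if (length(msg)) msg else TRUE
})

#' Unweighted undirected brain graph at a fixed cost
#'
#' Connected graph on the shared region set with exactly the budgeted edge
#' count (MST backbone plus strongest remaining absolute correlations).
#'
#' @slot graph igraph object (undirected, simple).
#' @slot cost fraction of all node pairs retained as edges.
#' @slot provenance free-form tags (subject, timepoint, ...).
#' @export
setClass("BrainGraph",
  representation(
    graph = "igraph",
    cost = "numeric",
    provenance = "character"
  )
)

setValidity("BrainGraph", function(object) {
  g <- object@graph
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (igraph::any_loop(g) || igraph::any_multiple(g)) {
    msg <- c(msg, "graph must be simple (no loops or duplicate edges)")
  }
  if (igraph::vcount(g) >= 2 && !igraph::is_connected(g)) {
    msg <- c(msg, "graph must be connected")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic hub-structured template network
#'
#' Ground-truth connectome emulation used by the synthetic-cohort module: a
#' connected graph with an exact edge budget in which a designated node set
#' holds the largest degrees (the planted hubs).
#'
#' @slot graph igraph object.
#' @slot hubIds integer indices of the planted hubs.
#' @slot edgeBudget target edge count.
#' @export
setClass("TemplateNetwork",
  representation(
    graph = "igraph",
    hubIds = "integer",
    edgeBudget = "integer"
  )
)

setValidity("TemplateNetwork", function(object) {
  g <- object@graph
  msg <- character()
  if (!igraph::is_connected(g)) msg <- c(msg, "template must be connected")
  if (any(object@hubIds < 1 | object@hubIds > igraph::vcount(g))) {
    msg <- c(msg, "hubIds out of range")
  }
  if (length(msg)) msg else TRUE
})

#' Per-node values of one graph metric
#'
#' @slot metric one of "degree", "clustering", "local_efficiency",
#'   "betweenness".
#' @slot values numeric vector aligned to the shared region ordering.
#' @slot provenance free-form tags.
#' @export
setClass("NodalMetricProfile",
  representation(
    metric = "character",
    values = "numeric",
    provenance = "character"
  )
)

setValidity("NodalMetricProfile", function(object) {
  msg <- character()
  if (length(object@metric) != 1) msg <- c(msg, "metric must be a single name")
  if (any(is.na(object@values))) msg <- c(msg, "values must be non-missing")
  if (length(msg)) msg else TRUE
})

#' Reference (healthy-cohort mean) nodal profile
#'
#' Node-wise arithmetic mean of a cohort of individual metric profiles; the
#' x-axis of the hub-disruption regression.
#'
#' @slot metric metric name shared by all cohort members.
#' @slot values per-node mean values.
#' @slot cohortSize number of profiles averaged.
#' @export
setClass("ReferenceProfile",
  representation(
    metric = "character",
    values = "numeric",
    cohortSize = "integer"
  )
)

setValidity("ReferenceProfile", function(object) {
  if (object@cohortSize < 1) "cohortSize must be >= 1" else TRUE
})

#' Hub disruption index estimate
#'
#' OLS fit of per-node differences (individual minus reference) on the
#' reference nodal means; the slope is the HDI.
#'
#' @slot slope the HDI.
#' @slot intercept intercept of the nodal-difference regression.
#' @slot differences per-node individual-minus-reference values.
#' @slot r2 coefficient of determination of the fit.
#' @slot se standard error of the slope.
#' @slot metric metric name.
#' @slot provenance subject/timepoint tags.
#' @export
setClass("HDIEstimate",
  representation(
    slope = "numeric",
    intercept = "numeric",
    differences = "numeric",
    r2 = "numeric",
    se = "numeric",
    metric = "character",
    provenance = "character"
  )
)

setValidity("HDIEstimate", function(object) {
  if (!is.finite(object@slope)) "slope must be finite" else TRUE
})

#' Linear mixed-effects HDI model fit
#'
#' REML fit of hdi ~ consciousness * time + (1 | subject) with cluster
#' (subject) bootstrap confidence intervals and p-values.
#'
#' @slot coefficients data.frame with estimate, CI bounds and bootstrap p
#'   per fixed effect.
#' @slot randomInterceptSD between-subject standard deviation.
#' @slot residualSD residual standard deviation.
#' @slot nBoot number of bootstrap draws.
#' @slot fit the underlying lmerMod object.
#' @export
setClass("MixedModelFit",
  representation(
    coefficients = "data.frame",
    randomInterceptSD = "numeric",
    residualSD = "numeric",
    nBoot = "integer",
    fit = "ANY"
  )
)

setValidity("MixedModelFit", function(object) {
  cf <- object@coefficients
  need <- c("term", "estimate", "ci_low", "ci_high", "p_value")
  if (!all(need %in% names(cf))) {
    return("coefficients must have term/estimate/ci_low/ci_high/p_value")
  }
  bad <- with(cf, ci_low > estimate + 1e-12 | ci_high < estimate - 1e-12)
  if (any(bad, na.rm = TRUE)) {
    return("each CI must contain its point estimate")
  }
  TRUE
})
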