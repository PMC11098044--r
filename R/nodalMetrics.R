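# Per-node metrics on unweighted undirected graphs. Degree and betweenness
# probe integration (how a node reaches the rest of the network), clustering
# and local efficiency probe segregation (how interconnected its immediate
# neighbourhood is). A hub is a node ranking high on any of these.

.as_igraph <- function(g) {
  if (is(g, "BrainGraph") || is(g, "TemplateNetwork")) {
    return(asIgraph(g))
  }
  if (inherits(g, "igraph")) {
    return(g)
  }
  stopf("expected a BrainGraph, TemplateNetwork or igraph object")
}

.provenance_of <- function(g) {
  if (is(g, "BrainGraph")) g@provenance else character()
}

#' Degree of every node
#'
#' Number of edges linking each node to the rest of the network; degrees
#' always sum to twice the edge count.
#'
#' @param g a [BrainGraph-class], [TemplateNetwork-class] or igraph object.
#' @return a [NodalMetricProfile-class] with metric `"degree"`.
#' @export
degreeProfile <- function(g) {
  ig <- .as_igraph(g)
  new("NodalMetricProfile",
    metric = "degree",
    values = as.numeric(igraph::degree(ig)),
    provenance = .provenance_of(g)
  )
}

#' Clustering coefficient or local efficiency of every node
#'
#' `variant = "coefficient"`: fraction of realised edges among each node's
#' neighbour pairs (triangles over `k(k-1)/2`). `variant =
#' "local_efficiency"`: mean inverse shortest-path length within the
#' neighbourhood subgraph. Nodes with fewer than two neighbours score 0
#' under both variants, keeping profiles dense.
#'
#' @param g a [BrainGraph-class], [TemplateNetwork-class] or igraph object.
#' @param variant `"coefficient"` (default) or `"local_efficiency"`.
#' @return a [NodalMetricProfile-class].
#' @export
clusteringProfile <- function(g, variant = c("coefficient", "local_efficiency")) {
  variant <- match.arg(variant)
  ig <- .as_igraph(g)
  n <- igraph::vcount(ig)
  if (variant == "coefficient") {
    v <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
    v[is.na(v)] <- 0
    metric <- "clustering"
  } else {
    v <- vapply(seq_len(n), function(i) {
      nb <- as.integer(igraph::neighbors(ig, i))
      k <- length(nb)
      if (k < 2) {
        return(0)
      }
      sub <- igraph::induced_subgraph(ig, nb)
      d <- igraph::distances(sub)
      inv <- 1 / d[upper.tri(d)]
      inv[!is.finite(inv)] <- 0
      mean(inv) # mean over unordered neighbour pairs
    }, numeric(1))
    metric <- "local_efficiency"
  }
  new("NodalMetricProfile",
    metric = metric, values = as.numeric(v),
    provenance = .provenance_of(g)
  )
}

#' Betweenness centrality of every node
#'
#' Fraction of shortest paths between all other node pairs passing through
#' each node, with fractional counting over equal-length paths; normalised
#' by `(n-1)(n-2)/2` by default. The HDI is invariant to this common scale
#' factor, so normalisation only affects the axis units.
#'
#' @param g a [BrainGraph-class], [TemplateNetwork-class] or igraph object.
#' @param normalized divide by `(n-1)(n-2)/2` (default TRUE).
#' @return a [NodalMetricProfile-class] with metric `"betweenness"`.
#' @export
betweennessProfile <- function(g, normalized = TRUE) {
  ig <- .as_igraph(g)
  v <- igraph::betweenness(ig, directed = FALSE, normalized = normalized)
  new("NodalMetricProfile",
    metric = "betweenness", values = as.numeric(v),
    provenance = .provenance_of(g)
  )
}

#' Modularity of a Louvain partition
#'
#' Auxiliary global summary: Newman modularity Q of a seeded Louvain
#' community partition.
#'
#' @param g a [BrainGraph-class], [TemplateNetwork-class] or igraph object.
#' @param seed integer seed for the (stochastic) Louvain sweep.
#' @return list with `Q` (scalar) and `membership` (integer vector).
#' @export
modularityScore <- function(g, seed = 1L) {
  ig <- .as_igraph(g)
  cl <- with_seed(seed, igraph::cluster_louvain(ig))
  list(
    Q = igraph::modularity(ig, igraph::membership(cl)),
    membership = as.integer(igraph::membership(cl))
  )
}

#' Top-fraction nodes of a metric profile
#'
#' The hub set of a profile: nodes in the top `topFraction` by metric value
#' (`ceiling(topFraction * n)` of them), ties resolved in favour of the
#' smaller node index.
#'
#' @param profile a [NodalMetricProfile-class] or numeric vector.
#' @param topFraction fraction in (0, 1).
#' @return integer vector of node indices.
#' @export
hubSet <- function(profile, topFraction = 0.1) {
  if (is(profile, "NodalMetricProfile")) profile <- profile@values
  if (!is.numeric(profile)) stopf("profile must be numeric")
  if (!is.numeric(topFraction) || topFraction <= 0 || topFraction >= 1) {
    stopf("topFraction must lie in (0, 1)")
  }
  k <- ceiling(topFraction * length(profile))
  order(-profile, seq_along(profile))[seq_len(k)]
}

#' All nodal metric profiles of one graph
#'
#' Convenience wrapper computing degree, the selected clustering variant and
#' betweenness in one call.
#'
#' @param g a [BrainGraph-class], [TemplateNetwork-class] or igraph object.
#' @param clusteringVariant passed to [clusteringProfile()].
#' @return named list of [NodalMetricProfile-class] objects.
#' @export
nodalMetrics <- function(g, clusteringVariant = "coefficient") {
  cp <- clusteringProfile(g, variant = clusteringVariant)
  list(
    degree = degreeProfile(g),
    clustering = cp,
    betweenness = betweennessProfile(g)
  )
}
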