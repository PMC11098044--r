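# From a correlation matrix to a connected unweighted graph at a fixed cost:
# a maximum-|r| spanning tree guarantees connectedness, then the strongest
# remaining absolute correlations are added until the edge budget is met.

#' Edge budget implied by a cost
#'
#' The cost of a graph is the fraction of all possible node pairs kept as
#' edges. The budget is `floor(cost * n(n-1)/2)`, never below `n - 1` so a
#' spanning tree always fits; 107 regions at 5% cost give 283 edges.
#'
#' @param nNodes node count (>= 2).
#' @param cost fraction in (0, 1].
#' @return integer edge count.
#' @examples
#' costToEdgeCount(107, 0.05) # 283
#' @export
costToEdgeCount <- function(nNodes, cost) {
  if (!is_count(nNodes, min = 2)) stopf("nNodes must be an integer >= 2")
  if (!is.numeric(cost) || length(cost) != 1 || cost <= 0 || cost > 1) {
    stopf("cost must lie in (0, 1]")
  }
  budget <- floor(cost * nNodes * (nNodes - 1) / 2)
  if (budget < nNodes - 1) {
    warnf(
      "cost %g yields %d edges, below the %d needed for a spanning tree; raised",
      cost, budget, nNodes - 1
    )
    budget <- nNodes - 1
  }
  as.integer(budget)
}

# Internal: deterministic maximum-|r| spanning tree as a 2-column edge
# matrix (i < j). Pairs are ranked by (|r| desc, i, j) and that rank is fed
# to igraph::mst as a unique integer weight, so the tree is unique and the
# documented tie rule holds. Regions with an all-NA row attach afterwards by
# their single best available correlation, or to the lowest-index attached
# node if they have none.
.mst_edges <- function(m) {
  n <- nrow(m)
  if (n < 2) stopf("need at least 2 regions for a spanning tree")
  missing_region <- vapply(seq_len(n), function(r) {
    all(is.na(m[r, -r]))
  }, logical(1))
  present <- which(!missing_region)
  if (length(present) < 1) stopf("all regions missing")
  rk <- rank_pairs(m)
  keep <- !is.na(rk$absr) &
    !missing_region[rk$pairs[, 1]] & !missing_region[rk$pairs[, 2]]
  pp <- rk$pairs[keep, , drop = FALSE]
  if (length(present) >= 2) {
    # map present nodes to 1..k for igraph
    map <- integer(n)
    map[present] <- seq_along(present)
    g <- igraph::graph_from_edgelist(
      cbind(map[pp[, 1]], map[pp[, 2]]),
      directed = FALSE
    )
    igraph::E(g)$weight <- seq_len(nrow(pp)) # rank order: unique weights
    if (igraph::vcount(g) < length(present) || !igraph::is_connected(g)) {
      stopf("correlation matrix has missing entries that disconnect the MST")
    }
    tr <- igraph::mst(g, weights = igraph::E(g)$weight)
    te <- igraph::as_edgelist(tr, names = FALSE)
    edges <- cbind(present[te[, 1]], present[te[, 2]])
  } else {
    edges <- matrix(integer(0), 0, 2)
  }
  # attach missing regions by one edge each
  for (r in which(missing_region)) {
    row <- m[r, ]
    row[r] <- NA
    if (any(!is.na(row))) {
      partner <- which.max(abs(row)) # first max: deterministic
    } else {
      partner <- setdiff(seq_len(n), r)[1]
    }
    edges <- rbind(edges, c(r, partner))
  }
  t(apply(edges, 1, sort))
}

#' Maximum-correlation spanning tree backbone
#'
#' The spanning tree over the strongest absolute correlations (minimum
#' spanning tree under distance `1 - |r|`), which keeps the thresholded
#' graph fully connected. Regions with no usable correlations are attached
#' by a single edge.
#'
#' @param m a [CorrelationMatrix-class] or plain square matrix.
#' @return 2-column integer matrix of edges, each row sorted `i < j`.
#' @export
mstBackbone <- function(m) {
  if (is(m, "CorrelationMatrix")) m <- m@matrix
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  .mst_edges(m)
}

#' Threshold a correlation matrix to a fixed-cost connected graph
#'
#' Keeps the spanning-tree backbone, then adds the highest-|r| remaining
#' pairs until exactly [costToEdgeCount()] edges are present. Ties are
#' broken by (|r| descending, smaller index, larger index), so the output
#' is bit-reproducible, and the edge set at a lower cost is always a subset
#' of the edge set at a higher cost.
#'
#' @param m a [CorrelationMatrix-class] or plain square matrix.
#' @param cost fraction of node pairs retained (default 0.05).
#' @param provenance optional character tags stored on the graph.
#' @return a [BrainGraph-class] object.
#' @examples
#' set.seed(1)
#' r <- cor(matrix(rnorm(2000), 100, 20))
#' g <- thresholdToCost(r, cost = 0.2)
#' edgeCount(g)
#' @export
thresholdToCost <- function(m, cost = 0.05, provenance = character()) {
  if (is(m, "CorrelationMatrix")) m <- m@matrix
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  n <- nrow(m)
  budget <- costToEdgeCount(n, cost)
  tree <- .mst_edges(m)
  key <- tree[, 1] * (n + 1) + tree[, 2]
  rk <- rank_pairs(m)
  sel <- matrix(tree, ncol = 2)
  if (nrow(sel) < budget) {
    cand_key <- rk$pairs[, 1] * (n + 1) + rk$pairs[, 2]
    extra <- rk$pairs[!(cand_key %in% key) & !is.na(rk$absr), , drop = FALSE]
    need <- budget - nrow(sel)
    if (nrow(extra) < need) {
      stopf("not enough usable correlations to reach %d edges", budget)
    }
    sel <- rbind(sel, extra[seq_len(need), , drop = FALSE])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(sel))
  out <- new("BrainGraph",
    graph = g, cost = cost,
    provenance = as.character(provenance)
  )
  stopifnot(igraph::ecount(g) == budget)
  out
}
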