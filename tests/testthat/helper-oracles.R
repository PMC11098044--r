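# Brute-force enumeration oracles, independent of the implementations they
# check. All operate on tiny inputs where exhaustive enumeration is exact.

# Two-sided exact Mann-Whitney p by enumerating all group assignments of
# the pooled sample (no ties assumed).
oracle_mann_whitney_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  splits <- combn(length(pooled), n1)
  us <- apply(splits, 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Two-sided exact Wilcoxon signed-rank p by enumerating all 2^n sign
# patterns of the non-zero differences (no ties in |d| assumed).
oracle_signed_rank_p <- function(x1, x2) {
  d <- x1 - x2
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins: sum the probabilities not exceeding the
# observed one (with the customary 1e-7 tolerance).
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Normalised betweenness by exhaustive simple-path enumeration on an
# adjacency matrix (feasible for n <= 8). For every unordered pair, all
# simple paths are enumerated by DFS, shortest ones kept, and each interior
# node credited with its fraction.
oracle_betweenness <- function(adj, normalized = TRUE) {
  n <- nrow(adj)
  bc <- numeric(n)
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1]] <<- path
        return()
      }
      for (w in which(adj[v, ] > 0)) {
        if (!(w %in% path)) walk(c(path, w))
      }
    }
    walk(s)
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (!length(paths)) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        interior <- setdiff(p, c(s, t))
        bc[interior] <- bc[interior] + 1 / length(shortest)
      }
    }
  }
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  bc
}

# Closed-form OLS slope and intercept of y on x.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Random connected graph on n nodes with m extra edges beyond a spanning
# tree, as an adjacency matrix (test utility, not a generator under test).
random_connected_adj <- function(n, extra = 2) {
  adj <- matrix(0, n, n)
  for (v in 2:n) {
    u <- sample.int(v - 1, 1)
    adj[u, v] <- adj[v, u] <- 1
  }
  open <- which(upper.tri(adj) & adj == 0)
  if (extra > 0 && length(open)) {
    pick <- sample(open, min(extra, length(open)))
    adj[pick] <- 1
    adj <- pmax(adj, t(adj))
  }
  adj
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
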