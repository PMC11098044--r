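# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package route their randomness through this, so nothing leaks into (or
# depends on) global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# All unordered node pairs (i < j) of an n-node graph, as a 2-column matrix.
all_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(i = idx[, "row"], j = idx[, "col"])
}

# Deterministic ranking of node pairs by (|r| descending, i ascending,
# j ascending); NA correlations sort last. Returns the pair matrix in rank
# order together with the |r| values. This single ordering is used both for
# the MST backbone and for cost thresholding, making every emitted graph
# bit-reproducible.
rank_pairs <- function(m) {
  n <- nrow(m)
  p <- all_pairs(n)
  r <- abs(m[p])
  key <- ifelse(is.na(r), -Inf, r)
  o <- order(-key, p[, 1], p[, 2])
  list(pairs = p[o, , drop = FALSE], absr = r[o])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == round(x) && x >= min
}

is_fraction <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}
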