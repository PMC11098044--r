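# MODWT decomposition and scale-wise wavelet correlation.
#
# The maximal overlap discrete wavelet transform is implemented directly
# (pyramid algorithm with periodic boundary): it is the analytical core of
# the connectivity estimator, level-j details occupy the dyadic band
# [1/2^(j+1), 1/2^j] cycles per sample, every level keeps the length of the
# input, and energy is conserved exactly.

# Scaling (low-pass) filters; wavelet filters follow by quadrature
# mirroring. Daubechies extremal phase, by number of taps.
.scaling_filters <- list(
  haar = c(1, 1) / sqrt(2),
  d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
  d6 = c(
    0.3326705529509569, 0.8068915093133388, 0.4598775021193313,
    -0.1350110200103908, -0.0854412738822415, 0.0352262918821007
  )
)

.wavelet_filter_pair <- function(filter) {
  g <- .scaling_filters[[filter]]
  if (is.null(g)) {
    stopf(
      "unknown wavelet filter '%s' (available: %s)", filter,
      paste(names(.scaling_filters), collapse = ", ")
    )
  }
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1) # quadrature mirror
  # MODWT rescaling
  list(g = g / sqrt(2), h = h / sqrt(2), L = L)
}

# One MODWT pyramid step at level j: circular filtering with the filter
# upsampled by 2^(j-1).
.modwt_step <- function(v, f, j) {
  n <- length(v)
  out <- numeric(n)
  shift <- 2^(j - 1)
  for (l in seq_along(f)) {
    idx <- ((seq_len(n) - 1 - (l - 1) * shift) %% n) + 1
    out <- out + f[l] * v[idx]
  }
  out
}

.imodwt_step <- function(w, v, h, g, j) {
  n <- length(v)
  out <- numeric(n)
  shift <- 2^(j - 1)
  for (l in seq_along(g)) {
    idx <- ((seq_len(n) - 1 + (l - 1) * shift) %% n) + 1
    out <- out + h[l] * w[idx] + g[l] * v[idx]
  }
  out
}

#' Maximal overlap discrete wavelet transform
#'
#' Decomposes a signal into `nLevels` detail series plus a final smooth,
#' using circular (periodic) boundary handling. Each level has the same
#' length as the input and the transform conserves energy exactly; level-j
#' details capture the frequency band `[1/2^(j+1), 1/2^j]` cycles per
#' sample. The first `L_j - 1` coefficients of each level are affected by
#' the circular wrap (with `L_j = (2^j - 1)(L - 1) + 1` for an `L`-tap
#' filter) and their count is reported so correlation estimation can skip
#' them.
#'
#' @param x numeric vector, length at least `2^nLevels`.
#' @param filter `"haar"`, `"d4"` (default) or `"d6"`.
#' @param nLevels decomposition depth (default 4).
#' @return a list with elements `details` (list of length `nLevels`),
#'   `smooth`, `filter`, `nLevels`, and `boundary` (per-level count of
#'   boundary-affected coefficients).
#' @seealso [imodwt()], [waveletCorrelationMatrix()]
#' @examples
#' d <- modwt(sin(2 * pi * 0.05 * seq_len(256)))
#' sapply(d$details, function(w) sum(w^2)) # energy per scale
#' @export
modwt <- function(x, filter = "d4", nLevels = 4) {
  if (!is.numeric(x) || any(is.na(x))) stopf("input series must be numeric and complete")
  if (!is_count(nLevels, min = 1)) stopf("nLevels must be a positive integer")
  n <- length(x)
  if (n < 2^nLevels) {
    stopf("series of length %d too short for %d levels (need >= %d)", n, nLevels, 2^nLevels)
  }
  f <- .wavelet_filter_pair(filter)
  details <- vector("list", nLevels)
  v <- as.numeric(x)
  boundary <- integer(nLevels)
  for (j in seq_len(nLevels)) {
    details[[j]] <- .modwt_step(v, f$h, j)
    v <- .modwt_step(v, f$g, j)
    Lj <- (2^j - 1) * (f$L - 1) + 1
    boundary[j] <- min(Lj - 1, n)
  }
  list(
    details = details, smooth = v, filter = filter,
    nLevels = nLevels, boundary = boundary
  )
}

#' Inverse MODWT
#'
#' Reconstructs the original series from a [modwt()] decomposition; the
#' round trip is exact to numerical precision.
#'
#' @param d a decomposition as returned by [modwt()].
#' @return numeric vector of the original length.
#' @export
imodwt <- function(d) {
  f <- .wavelet_filter_pair(d$filter)
  v <- d$smooth
  for (j in rev(seq_len(d$nLevels))) {
    v <- .imodwt_step(d$details[[j]], v, f$h, f$g, j)
  }
  v
}

#' Frequency band of one wavelet level
#'
#' Level `j` of a dyadic decomposition of a series sampled every
#' `samplingInterval` seconds covers `(1/(2^(j+1) dt), 1/(2^j dt))` Hz.
#'
#' @param samplingInterval seconds between samples.
#' @param level wavelet level (1 = highest frequencies).
#' @return numeric vector `c(f_low, f_high)` in Hz.
#' @examples
#' scaleFrequencyBand(2.0, 3) # c(0.03125, 0.0625)
#' @export
scaleFrequencyBand <- function(samplingInterval, level) {
  if (samplingInterval <= 0) stopf("samplingInterval must be positive")
  if (!is_count(level, min = 1)) stopf("level must be a positive integer")
  c(1 / (2^(level + 1) * samplingInterval), 1 / (2^level * samplingInterval))
}

#' Choose the wavelet level matching a target frequency band
#'
#' Returns the level whose dyadic band overlaps the target band the most.
#' The default target, 0.032-0.065 Hz, is the low-frequency interval that
#' carries the bulk of resting-state BOLD covariance; with a repetition
#' time near 2 s this selects level 3.
#'
#' @param samplingInterval seconds between volumes.
#' @param targetBand length-2 numeric, Hz.
#' @param maxLevel deepest level considered (default 8).
#' @return integer level.
#' @examples
#' selectScale(2.0) # 3
#' selectScale(1.0) # 4
#' @export
selectScale <- function(samplingInterval, targetBand = c(0.032, 0.065),
                        maxLevel = 8) {
  if (length(targetBand) != 2 || targetBand[1] >= targetBand[2]) {
    stopf("targetBand must be c(low, high) with low < high")
  }
  overlap <- vapply(seq_len(maxLevel), function(j) {
    b <- scaleFrequencyBand(samplingInterval, j)
    max(0, min(b[2], targetBand[2]) - max(b[1], targetBand[1]))
  }, numeric(1))
  if (all(overlap <= 0)) {
    stopf(
      "no wavelet level in 1..%d overlaps the band [%g, %g] Hz at TR = %g s",
      maxLevel, targetBand[1], targetBand[2], samplingInterval
    )
  }
  which.max(overlap)
}

#' Wavelet correlation matrix at one scale
#'
#' Pearson correlation of level-`level` MODWT detail coefficients for every
#' pair of regions, excluding the boundary-affected coefficients. Regions
#' whose series are entirely missing propagate as NA rows/columns, to be
#' attached by a single edge during graph construction.
#'
#' @param ts a [RegionalTimeSeries-class] object.
#' @param level wavelet level; default picks the level matching the
#'   0.032-0.065 Hz band via [selectScale()].
#' @param filter wavelet filter name (default `"d4"`).
#' @param minCoefficients minimum usable (non-boundary) coefficients
#'   required (default 30).
#' @return a [CorrelationMatrix-class] object.
#' @export
waveletCorrelationMatrix <- function(ts, level = NULL, filter = "d4",
                                     minCoefficients = 30) {
  stopifnot(is(ts, "RegionalTimeSeries"))
  x <- ts@data
  if (is.null(level)) level <- selectScale(ts@samplingInterval)
  n <- nrow(x)
  f <- .wavelet_filter_pair(filter)
  Lj <- (2^level - 1) * (f$L - 1) + 1
  usable <- n - min(Lj - 1, n)
  if (usable < minCoefficients) {
    stopf(
      "only %d non-boundary coefficients at level %d (need >= %d)",
      usable, level, minCoefficients
    )
  }
  missing_region <- apply(x, 2, function(col) all(is.na(col)))
  p <- ncol(x)
  det <- matrix(NA_real_, usable, p)
  for (r in seq_len(p)) {
    if (missing_region[r]) next
    d <- modwt(x[, r], filter = filter, nLevels = level)
    det[, r] <- tail(d$details[[level]], usable)
  }
  m <- suppressWarnings(stats::cor(det, use = "everything"))
  diag(m) <- 1
  # zero-variance (constant) regions yield NaN; treat as missing
  m[is.nan(m)] <- NA_real_
  # missing regions propagate as fully-NA rows/columns
  m[missing_region, ] <- NA_real_
  m[, missing_region] <- NA_real_
  dimnames(m) <- list(ts@regionLabels, ts@regionLabels)
  new("CorrelationMatrix",
    matrix = m, scale = as.integer(level),
    nEffective = as.integer(usable)
  )
}

#' Mean off-diagonal correlation
#'
#' Mean of the upper-triangle entries of a correlation matrix — the
#' per-subject summary used to check that overall connectivity strength is
#' comparable across groups before any graph analysis.
#'
#' @param m a [CorrelationMatrix-class] or plain square matrix.
#' @return numeric scalar (NA entries are dropped).
#' @export
meanCorrelation <- function(m) {
  if (is(m, "CorrelationMatrix")) m <- m@matrix
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  mean(m[upper.tri(m)], na.rm = TRUE)
}
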