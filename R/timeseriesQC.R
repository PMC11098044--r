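# Imaging-space inputs to clean regional series: grey-matter-probability
# weighted parcel averaging, ART-style outlier flagging (composite motion
# and global-signal change), dataset rejection, and nuisance regression.

.read_img <- function(x) {
  if (is.character(x)) {
    return(as.array(RNifti::readNifti(x)))
  }
  as.array(x)
}

#' Extract regional time series from a 4D BOLD image
#'
#' For each atlas label, averages the BOLD signal of its voxels weighted by
#' their grey-matter probability: `sum(p_v * s_v(t)) / sum(p_v)`. The
#' weighting suppresses white-matter and CSF contamination. Labels whose
#' total probability is zero produce all-NA columns with a warning; label 0
#' is background.
#'
#' @param bold 4D array or NIfTI path (x, y, z, t).
#' @param atlas 3D integer label array or NIfTI path, same grid.
#' @param gmProb 3D probability array or NIfTI path, same grid, values in
#'   \\[0, 1\\]; NULL means uniform weights (plain parcel mean).
#' @param samplingInterval repetition time in seconds (default 2).
#' @return a [RegionalTimeSeries-class], one column per label in ascending
#'   label order, labelled `"parcel_<label>"`.
#' @export
extractRegionalTimeSeries <- function(bold, atlas, gmProb = NULL,
                                      samplingInterval = 2) {
  bold <- .read_img(bold)
  atlas <- .read_img(atlas)
  if (length(dim(bold)) != 4) stopf("bold must be a 4D (x, y, z, t) image")
  if (!all(dim(bold)[1:3] == dim(atlas))) {
    stopf("bold and atlas grids differ")
  }
  if (is.null(gmProb)) {
    gmProb <- array(1, dim(atlas))
  } else {
    gmProb <- .read_img(gmProb)
    if (!all(dim(gmProb) == dim(atlas))) stopf("gmProb grid differs from atlas")
    if (any(gmProb < 0 | gmProb > 1)) stopf("gmProb values must lie in [0, 1]")
  }
  if (any(atlas != round(atlas)) || any(atlas < 0)) {
    stopf("atlas labels must be non-negative integers")
  }
  labels <- sort(unique(as.vector(atlas)))
  labels <- labels[labels > 0]
  if (!length(labels)) stopf("atlas contains no non-background labels")
  nT <- dim(bold)[4]
  vox <- prod(dim(atlas))
  boldMat <- matrix(bold, vox, nT)
  out <- matrix(NA_real_, nT, length(labels))
  for (k in seq_along(labels)) {
    idx <- which(as.vector(atlas) == labels[k])
    w <- as.vector(gmProb)[idx]
    sw <- sum(w)
    if (sw == 0) {
      warnf("parcel %d has zero total grey-matter probability; emitting NA", labels[k])
      next
    }
    out[, k] <- as.vector(crossprod(boldMat[idx, , drop = FALSE], w)) / sw
  }
  new("RegionalTimeSeries",
    data = out,
    regionLabels = sprintf("parcel_%d", labels),
    samplingInterval = samplingInterval
  )
}

#' Composite inter-volume displacement
#'
#' Euclidean norm of the translation change plus the arc displacement of
#' the rotation change on a `headRadiusMm` sphere (the ART toolbox
#' composite convention); the first volume has displacement 0.
#'
#' @param motion volumes x 6 matrix (3 translations mm, 3 rotations rad).
#' @param headRadiusMm rotation lever arm in millimetres (default 65).
#' @return numeric vector of per-volume displacements in mm.
#' @export
compositeMotion <- function(motion, headRadiusMm = 65) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stopf("motion trace must have 6 columns")
  d <- diff(motion)
  c(0, sqrt(rowSums(d[, 1:3, drop = FALSE]^2)) +
    headRadiusMm * sqrt(rowSums(d[, 4:6, drop = FALSE]^2)))
}

#' Flag outlier volumes by motion and global-signal change
#'
#' A volume is flagged if its composite inter-volume displacement
#' (translation norm plus rotation arc at a 65 mm head radius) exceeds
#' `motionMmThreshold`, or if the absolute change of the global signal from
#' the previous volume exceeds `signalSdThreshold` standard deviations of
#' the global signal. Both criteria are inter-volume, so the first volume
#' is never flagged. Flagging is invariant to adding a constant to the
#' global signal.
#'
#' @param motion volumes x 6 motion trace.
#' @param globalSignal per-volume mean signal (same length), or NULL to
#'   use motion criteria only.
#' @param motionMmThreshold millimetres (default 5).
#' @param signalSdThreshold SD multiples (default 3).
#' @param headRadiusMm rotation lever arm (default 65).
#' @return logical vector, TRUE = outlier; attributes `nFlagged` and
#'   `fractionFlagged` summarise it.
#' @export
flagOutlierVolumes <- function(motion, globalSignal = NULL,
                               motionMmThreshold = 5, signalSdThreshold = 3,
                               headRadiusMm = 65) {
  motion <- as.matrix(motion)
  n <- nrow(motion)
  if (n < 2) stopf("need at least 2 volumes")
  flags <- compositeMotion(motion, headRadiusMm) > motionMmThreshold
  if (!is.null(globalSignal)) {
    if (length(globalSignal) != n) {
      stopf("globalSignal length must match the motion trace")
    }
    s <- sd(globalSignal)
    if (s > 0) {
      flags <- flags | c(FALSE, abs(diff(globalSignal)) > signalSdThreshold * s)
    }
  }
  flags[1] <- FALSE
  structure(flags,
    nFlagged = sum(flags),
    fractionFlagged = mean(flags)
  )
}

#' Keep or reject a dataset by its outlier fraction
#'
#' A run is rejected when strictly more than `maxFraction` of its volumes
#' are flagged (default 10%): 11 of 100 flagged rejects, 10 of 100 keeps.
#'
#' @param mask logical outlier mask from [flagOutlierVolumes()].
#' @param maxFraction rejection threshold (default 0.10).
#' @return TRUE to keep, FALSE to reject; attribute `fractionFlagged`
#'   reports the fraction.
#' @export
rejectDataset <- function(mask, maxFraction = 0.10) {
  mask <- as.logical(mask)
  frac <- mean(mask)
  structure(frac <= maxFraction, fractionFlagged = frac)
}

#' Regress nuisance signals out of regional time series
#'
#' Per region, returns the residual of an OLS regression on an intercept,
#' the six motion parameters, and one indicator column per flagged volume.
#' The indicators absorb flagged volumes completely, so their residuals are
#' exactly zero; the projection is idempotent and the residuals are
#' orthogonal to every regressor.
#'
#' @param ts a [RegionalTimeSeries-class].
#' @param motion volumes x 6 motion trace.
#' @param mask logical outlier mask (NULL = none).
#' @return a cleaned [RegionalTimeSeries-class].
#' @export
regressNuisance <- function(ts, motion, mask = NULL) {
  stopifnot(is(ts, "RegionalTimeSeries"))
  x <- ts@data
  n <- nrow(x)
  motion <- as.matrix(motion)
  if (nrow(motion) != n) stopf("motion trace and series lengths differ")
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (length(mask) != n) stopf("mask length must match the series")
  design <- cbind(1, motion)
  for (t in which(mask)) {
    ind <- numeric(n)
    ind[t] <- 1
    design <- cbind(design, ind)
  }
  q <- qr(design)
  if (q$rank < ncol(design)) {
    stopf("rank-deficient nuisance design (e.g. all volumes flagged)")
  }
  resid <- x - design %*% qr.coef(q, x)
  resid[mask, ] <- 0 # exact zero, not numerical noise
  new("RegionalTimeSeries",
    data = resid, regionLabels = ts@regionLabels,
    samplingInterval = ts@samplingInterval
  )
}
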