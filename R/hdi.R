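# The hub disruption index. For each node, plot the individual-minus-
# reference metric value (y) against the reference cohort mean (x); the OLS
# slope of that cloud is the HDI. A healthy-looking graph sits near a
# horizontal line (HDI = 0); a disrupted one — hubs losing value, non-hubs
# gaining — tilts the line negative.

#' Reference (cohort-mean) nodal profile
#'
#' Node-wise arithmetic mean across a cohort of individual metric profiles,
#' typically the healthy-subject group. All members must share the metric
#' and the node ordering.
#'
#' @param cohort list of [NodalMetricProfile-class] objects.
#' @return a [ReferenceProfile-class].
#' @export
referenceProfile <- function(cohort) {
  if (!is.list(cohort) || length(cohort) < 1) {
    stopf("cohort must be a non-empty list of NodalMetricProfile objects")
  }
  stopifnot(all(vapply(cohort, is, logical(1), "NodalMetricProfile")))
  metrics <- unique(vapply(cohort, metricName, character(1)))
  if (length(metrics) != 1) {
    stopf("mixed metrics in reference cohort: %s", paste(metrics, collapse = ", "))
  }
  lens <- unique(vapply(cohort, function(p) length(p@values), integer(1)))
  if (length(lens) != 1) stopf("profiles have inconsistent node counts")
  vals <- rowMeans(vapply(cohort, metricValues, numeric(lens)))
  new("ReferenceProfile",
    metric = metrics, values = vals,
    cohortSize = length(cohort)
  )
}

#' Hub disruption index of one individual profile
#'
#' Ordinary least squares with intercept of `y = individual - reference` on
#' `x = reference` over all nodes. The slope is the HDI; intercept, per-node
#' differences, R-squared and the slope standard error are kept for
#' diagnostics.
#'
#' @param individual a [NodalMetricProfile-class].
#' @param ref a [ReferenceProfile-class] with the same metric and ordering.
#' @param provenance optional character tags.
#' @return an [HDIEstimate-class].
#' @examples
#' ref <- new("ReferenceProfile",
#'   metric = "degree",
#'   values = c(1, 2, 3, 4), cohortSize = 2L
#' )
#' ind <- new("NodalMetricProfile",
#'   metric = "degree",
#'   values = c(4, 3, 2, 1), provenance = character()
#' )
#' hdi(hdiIndex(ind, ref)) # -2
#' @export
hdiIndex <- function(individual, ref, provenance = character()) {
  stopifnot(is(individual, "NodalMetricProfile"), is(ref, "ReferenceProfile"))
  if (metricName(individual) != metricName(ref)) {
    stopf(
      "metric mismatch: individual is '%s', reference is '%s'",
      metricName(individual), metricName(ref)
    )
  }
  x <- ref@values
  y <- individual@values - x
  if (length(x) != length(y)) stopf("node orderings differ in length")
  if (sd(x) == 0) stopf("degenerate reference: all nodal values equal, slope unidentifiable")
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- sum(xc * y) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  new("HDIEstimate",
    slope = slope, intercept = intercept, differences = y,
    r2 = r2, se = se, metric = metricName(individual),
    provenance = as.character(provenance)
  )
}

#' HDI table for a patient cohort against a reference cohort
#'
#' One HDI estimate per subject and metric. Profiles are supplied as a list
#' of per-subject named lists of [NodalMetricProfile-class] objects (as
#' produced by [nodalMetrics()]). When a subject is also a member of the
#' reference cohort and `looForReferenceMembers` is TRUE, that subject is
#' excluded from their own reference mean, avoiding self-bias in the
#' healthy group's HDI spread.
#'
#' @param subjects named list: subject id -> named list of profiles.
#' @param referenceSubjects character vector of subject ids forming the
#'   reference cohort (must be names of `subjects`).
#' @param looForReferenceMembers leave-one-out referencing for reference
#'   members (default TRUE).
#' @return data.frame with columns subject, metric, hdi, intercept, r2, se.
#' @export
hdiCohort <- function(subjects, referenceSubjects,
                      looForReferenceMembers = TRUE) {
  stopifnot(is.list(subjects), !is.null(names(subjects)))
  if (!all(referenceSubjects %in% names(subjects))) {
    stopf("referenceSubjects must all be present in subjects")
  }
  if (length(referenceSubjects) < 2) {
    stopf("reference cohort must have at least 2 members")
  }
  metrics <- names(subjects[[1]])
  rows <- list()
  for (met in metrics) {
    ref_profiles <- lapply(subjects[referenceSubjects], `[[`, met)
    for (sid in names(subjects)) {
      if (looForReferenceMembers && sid %in% referenceSubjects) {
        keep <- setdiff(referenceSubjects, sid)
        if (length(keep) < 2) stopf("reference cohort too small after leave-one-out")
        ref <- referenceProfile(lapply(subjects[keep], `[[`, met))
      } else {
        ref <- referenceProfile(ref_profiles)
      }
      est <- hdiIndex(subjects[[sid]][[met]], ref, provenance = sid)
      rows[[length(rows) + 1]] <- data.frame(
        subject = sid, metric = met, hdi = est@slope,
        intercept = est@intercept, r2 = est@r2, se = est@se,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
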