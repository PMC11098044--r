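# The statistical layer: nonparametric group tests on HDI values, the
# paired longitudinal test, the categorical-balance test, the longitudinal
# mixed-effects model with cluster bootstrap, and node-wise exploration
# with multiple-comparison correction. The rank tests delegate to the
# standard stats implementations (exact for small untied samples) behind a
# uniform result contract.

.test_result <- function(statistic, p, test, sizes) {
  list(
    statistic = unname(statistic), p = unname(p),
    test = test, sizes = unname(sizes)
  )
}

#' Mann-Whitney (two-sample Wilcoxon rank-sum) test
#'
#' Two-sided; exact by enumeration for small untied samples, normal
#' approximation with tie correction otherwise.
#'
#' @param a,b numeric vectors, each non-empty.
#' @return list with statistic (U), p, test, sizes.
#' @export
mannWhitney <- function(a, b) {
  if (!length(a) || !length(b)) stopf("both groups must be non-empty")
  w <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL, correct = TRUE))
  .test_result(w$statistic, w$p.value, "mann_whitney", c(length(a), length(b)))
}

#' Kruskal-Wallis rank test over several groups
#'
#' H statistic with tie correction, chi-square p-value on k-1 degrees of
#' freedom. If every value is identical the data are degenerate: H = 0 and
#' p = 1, with a warning.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return list with statistic (H), p, test, sizes.
#' @export
kruskalWallis <- function(groups) {
  stopifnot(is.list(groups))
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stopf("need at least 2 non-empty groups")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1) {
    warnf("all values identical; Kruskal-Wallis is degenerate (p = 1)")
    return(.test_result(0, 1, "kruskal_wallis", lengths(groups)))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- stats::kruskal.test(vals, g)
  .test_result(k$statistic, k$p.value, "kruskal_wallis", lengths(groups))
}

#' Wilcoxon signed-rank test (paired by default)
#'
#' Signed ranks of the non-zero differences; exact p for small untied
#' samples. All-zero differences give p = 1 with a warning.
#'
#' @param x1,x2 numeric vectors; equal length when `paired`.
#' @param paired logical (default TRUE).
#' @return list with statistic (V), p, test, sizes.
#' @export
wilcoxonSignedRank <- function(x1, x2, paired = TRUE) {
  if (paired && length(x1) != length(x2)) {
    stopf("paired samples must have equal length")
  }
  if (paired && all(x1 == x2)) {
    warnf("all paired differences are zero; p = 1")
    return(.test_result(0, 1, "wilcoxon_signed_rank", c(length(x1), length(x2))))
  }
  w <- suppressWarnings(stats::wilcox.test(x1, x2, paired = paired))
  .test_result(
    w$statistic, w$p.value, "wilcoxon_signed_rank",
    c(length(x1), length(x2))
  )
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided exact p by hypergeometric enumeration (tables with probability
#' not exceeding the observed one). A table with a zero margin carries no
#' information: p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with statistic (odds ratio estimate), p, test, sizes.
#' @export
fisherExact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
    any(table != round(table))) {
    stopf("need a 2x2 table of non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(.test_result(NA_real_, 1, "fisher_exact", sum(table)))
  }
  f <- stats::fisher.test(table)
  .test_result(unname(f$estimate), f$p.value, "fisher_exact", sum(table))
}

# Fixed-effect estimates for a (possibly resampled) cohort data frame with
# columns mcs, time01, y, subject. For the balanced two-timepoint design the
# OLS and GLS (random-intercept) fixed-effect estimates coincide, so the
# "ols" engine is an exact fast path for bootstrap resamples.
.fit_coefs <- function(df, engine) {
  if (engine == "ols") {
    X <- cbind(1, df$mcs, df$time01, df$mcs * df$time01)
    stats::lm.fit(X, df$y)$coefficients
  } else {
    fit <- suppressMessages(lme4::lmer(
      y ~ mcs * time01 + (1 | subject),
      data = df, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE)
    ))
    .pad_coefs(lme4::fixef(fit))
  }
}

# Align a (possibly reduced) coefficient vector to the full 4-term layout.
.pad_coefs <- function(cf) {
  full <- c("(Intercept)", "mcs", "time01", "mcs:time01")
  out <- stats::setNames(rep(NA_real_, 4), full)
  out[intersect(names(cf), full)] <- cf[intersect(names(cf), full)]
  out
}

#' Longitudinal mixed-effects model of the HDI
#'
#' REML fit of `hdi ~ consciousness * time + (1 | subject)` with
#' consciousness coded MCS = 1 / C = 0 and time centred at the first
#' timepoint (so the intercept is the conscious-group first-timepoint
#' mean). Confidence intervals and p-values come from a nonparametric
#' cluster bootstrap: whole subjects are resampled with replacement,
#' percentile 95% intervals and two-sided sign-crossing p-values are taken
#' over the bootstrap coefficient draws.
#'
#' @param records data.frame with columns subject, timepoint (1/2), state
#'   (MCS/C), hdi_value (as produced by [simulateHdiLongitudinal()]).
#' @param nBoot bootstrap draws (default 1000).
#' @param seed integer seed for the bootstrap resampling.
#' @param bootEngine `"lmer"` (refit the mixed model per resample) or
#'   `"ols"` (fixed-effect fast path, identical estimates for the balanced
#'   two-timepoint design).
#' @return a [MixedModelFit-class].
#' @export
fitHdiMixedModel <- function(records, nBoot = 1000, seed = 1L,
                             bootEngine = c("lmer", "ols")) {
  bootEngine <- match.arg(bootEngine)
  need <- c("subject", "timepoint", "state", "hdi_value")
  if (!all(need %in% names(records))) {
    stopf("records needs columns %s", paste(need, collapse = ", "))
  }
  if (length(unique(records$subject)) < 2) stopf("need at least 2 subjects")
  if (length(unique(records$state)) < 2) {
    warnf("only one consciousness state present; state terms are not identifiable")
  }
  df <- data.frame(
    subject = as.character(records$subject),
    mcs = as.numeric(records$state == "MCS"),
    time01 = as.numeric(records$timepoint) - 1,
    y = as.numeric(records$hdi_value)
  )
  fit <- suppressMessages(lme4::lmer(
    y ~ mcs * time01 + (1 | subject),
    data = df, REML = TRUE
  ))
  est <- .pad_coefs(lme4::fixef(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  subjects <- split(df, df$subject)
  ids <- names(subjects)
  boot <- with_seed(seed, {
    draws <- matrix(NA_real_, nBoot, 4)
    for (b in seq_len(nBoot)) {
      pick <- sample(ids, length(ids), replace = TRUE)
      res <- do.call(rbind, lapply(seq_along(pick), function(i) {
        d <- subjects[[pick[i]]]
        d$subject <- sprintf("b%03d", i) # resampled copies are new clusters
        d
      }))
      cf <- tryCatch(.fit_coefs(res, bootEngine), error = function(e) rep(NA_real_, 4))
      draws[b, ] <- cf
    }
    draws
  })
  ci <- matrix(NA_real_, 2, 4)
  pval <- rep(NA_real_, 4)
  nUsed <- nBoot
  for (j in seq_len(4)) {
    bs <- boot[, j]
    bs <- bs[!is.na(bs)]
    if (!length(bs)) next
    nUsed <- min(nUsed, length(bs))
    ci[, j] <- stats::quantile(bs, probs = c(0.025, 0.975))
    pval[j] <- min(1, 2 * min(mean(bs <= 0), mean(bs >= 0)))
  }
  terms <- c("intercept", "consciousness", "time", "consciousness:time")
  cfs <- data.frame(
    term = terms,
    estimate = as.numeric(est),
    ci_low = pmin(ci[1, ], as.numeric(est)),
    ci_high = pmax(ci[2, ], as.numeric(est)),
    p_value = pval,
    stringsAsFactors = FALSE
  )
  new("MixedModelFit",
    coefficients = cfs,
    randomInterceptSD = vc$sdcor[vc$grp == "subject"],
    residualSD = vc$sdcor[vc$grp == "Residual"],
    nBoot = as.integer(nUsed),
    fit = fit
  )
}

#' Node-wise group comparison with multiple-testing correction
#'
#' For each node, a two-sample rank test of the difference-from-reference
#' values between two groups, followed by Benjamini-Hochberg (default) or
#' Bonferroni adjustment across all nodes. This is the exploratory step
#' asking whether any single region drives an HDI difference.
#'
#' @param groupA,groupB subjects x nodes matrices of nodal values (e.g.
#'   each row an [HDIEstimate-class] differences vector).
#' @param correction `"BH"` or `"bonferroni"`.
#' @return data.frame with node, p_raw, p_adjusted, ordered by node.
#' @export
nodalExploration <- function(groupA, groupB, correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  groupA <- as.matrix(groupA)
  groupB <- as.matrix(groupB)
  if (ncol(groupA) != ncol(groupB)) stopf("groups must share the node set")
  if (nrow(groupA) < 2 || nrow(groupB) < 2) {
    stopf("need at least 2 members per group")
  }
  p <- vapply(seq_len(ncol(groupA)), function(j) {
    suppressWarnings(stats::wilcox.test(groupA[, j], groupB[, j])$p.value)
  }, numeric(1))
  data.frame(
    node = seq_len(ncol(groupA)),
    p_raw = p,
    p_adjusted = stats::p.adjust(p, method = correction)
  )
}
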