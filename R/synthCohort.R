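# Synthetic-cohort generation. No clinical dataset is distributable, so the
# package generates every input the pipeline needs: hub-structured template
# connectomes, covariance-consistent band-limited BOLD-like series,
# hub-disrupted patient networks, motion traces, and longitudinal HDI
# tables drawn from a known mixed model. Everything is seeded and
# bit-reproducible; no global RNG state is touched.

#' Hub-structured template connectome
#'
#' Builds a connected graph with an exact edge budget in which `nHubs`
#' designated nodes (indices 1..nHubs) hold the largest degrees. A
#' preferential-attachment tree (attachment probability proportional to
#' degree, with a bonus on designated hubs) is grown first, the remaining
#' budget is filled by degree-weighted pair sampling, and a deterministic
#' edge-swap repair guarantees the planted hubs outrank every other node.
#'
#' @param nRegions node count (default 107, a whole-brain parcellation
#'   scale).
#' @param nHubs number of planted hubs (default 10).
#' @param edgeBudget exact edge count; defaults to a 5% cost
#'   (`costToEdgeCount(nRegions, 0.05)`, 283 edges at 107 regions).
#' @param seed integer seed.
#' @return a [TemplateNetwork-class].
#' @examples
#' tpl <- makeTemplateGraph(20, 3, 40, seed = 7)
#' degreeProfile(tpl)
#' @export
makeTemplateGraph <- function(nRegions = 107, nHubs = 10,
                              edgeBudget = costToEdgeCount(nRegions, 0.05),
                              seed = 1L) {
  if (!is_count(nRegions, 2) || !is_count(nHubs, 1) || !is_count(edgeBudget, 1)) {
    stopf("nRegions, nHubs and edgeBudget must be positive integers")
  }
  if (nHubs >= nRegions) stopf("nHubs must be smaller than nRegions")
  maxE <- nRegions * (nRegions - 1) / 2
  if (edgeBudget < nRegions - 1 || edgeBudget > maxE) {
    stopf(
      "edgeBudget %d infeasible for %d nodes (must lie in [%d, %d])",
      edgeBudget, nRegions, nRegions - 1, maxE
    )
  }
  hubs <- seq_len(nHubs)
  bonus <- max(4, nRegions / 8)
  with_seed(seed, {
    adj <- matrix(FALSE, nRegions, nRegions)
    deg <- integer(nRegions)
    wt <- function() deg + 1 + bonus * (seq_len(nRegions) %in% hubs)
    # preferential-attachment spanning tree; hubs enter first
    for (t in 2:nRegions) {
      w <- wt()[seq_len(t - 1)]
      a <- sample.int(t - 1, 1, prob = w)
      adj[t, a] <- adj[a, t] <- TRUE
      deg[c(t, a)] <- deg[c(t, a)] + 1
    }
    tree <- which(adj & upper.tri(adj), arr.ind = TRUE)
    # fill the remaining budget by degree-weighted pair sampling
    extra <- edgeBudget - (nRegions - 1)
    tries <- 0
    while (extra > 0 && tries < 200 * edgeBudget) {
      w <- wt()
      uv <- sample.int(nRegions, 2, prob = w)
      u <- min(uv)
      v <- max(uv)
      tries <- tries + 1
      if (u != v && !adj[u, v]) {
        adj[u, v] <- adj[v, u] <- TRUE
        deg[c(u, v)] <- deg[c(u, v)] + 1
        extra <- extra - 1
      }
    }
    if (extra > 0) stopf("could not place %d edges within the try budget", extra)
    # repair: planted hubs must strictly outrank all other nodes by degree
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    for (iter in seq_len(50 * nRegions)) {
      deg <- igraph::degree(g)
      lo_hub <- hubs[which.min(deg[hubs])]
      nonhubs <- setdiff(seq_len(nRegions), hubs)
      hi_non <- nonhubs[which.max(deg[nonhubs])]
      if (min(deg[hubs]) > max(deg[nonhubs])) break
      moved <- FALSE
      for (x in as.integer(igraph::neighbors(g, hi_non))) {
        if (x == lo_hub || x %in% hubs) next
        if (igraph::get_edge_ids(g, c(lo_hub, x)) != 0) next
        g2 <- igraph::delete_edges(
          g, igraph::get_edge_ids(g, c(hi_non, x))
        )
        g2 <- igraph::add_edges(g2, c(lo_hub, x))
        if (igraph::is_connected(g2)) {
          g <- g2
          moved <- TRUE
          break
        }
      }
      if (!moved) {
        # fall back: move any non-hub edge endpoint onto the weak hub
        done <- FALSE
        el <- igraph::as_edgelist(g, names = FALSE)
        cand <- which(!(el[, 1] %in% hubs) & !(el[, 2] %in% hubs))
        for (e in cand) {
          u <- el[e, 1]
          v <- el[e, 2]
          if (igraph::get_edge_ids(g, c(lo_hub, v)) != 0) next
          g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
          g2 <- igraph::add_edges(g2, c(lo_hub, v))
          if (igraph::is_connected(g2)) {
            g <- g2
            done <- TRUE
            break
          }
        }
        if (!done) stopf("hub-ranking repair failed; try another seed or budget")
      }
    }
    deg <- igraph::degree(g)
    if (min(deg[hubs]) <= max(deg[-hubs])) {
      stopf("hub-ranking repair did not converge")
    }
    new("TemplateNetwork",
      graph = g, hubIds = as.integer(hubs),
      edgeBudget = as.integer(edgeBudget)
    )
  })
}

#' Region covariance implied by a template network
#'
#' Builds a correlation matrix in which adjacent regions co-fluctuate at
#' `edgeCorr` and non-adjacent regions only through shared neighbours:
#' starting from `I + edgeCorr * A`, the matrix is shrunk towards the
#' identity (`(S + d I) / (1 + d)`, preserving the unit diagonal) until the
#' smallest eigenvalue clears 1e-8, then scaled by `noiseVar`.
#'
#' @param template a [TemplateNetwork-class] (or igraph/adjacency matrix).
#' @param edgeCorr target correlation of adjacent pairs in (0, 1); the
#'   realised value is lower when shrinkage is needed for positive
#'   definiteness.
#' @param noiseVar marginal variance of every region (default 1).
#' @return symmetric positive-definite covariance matrix.
#' @export
graphToCovariance <- function(template, edgeCorr = 0.3, noiseVar = 1) {
  if (is(template, "TemplateNetwork")) {
    A <- as.matrix(igraph::as_adjacency_matrix(asIgraph(template)))
  } else if (inherits(template, "igraph")) {
    A <- as.matrix(igraph::as_adjacency_matrix(template))
  } else {
    A <- as.matrix(template)
  }
  if (!is.numeric(edgeCorr) || edgeCorr <= 0 || edgeCorr >= 1) {
    stopf("edgeCorr must lie strictly between 0 and 1")
  }
  if (noiseVar <= 0) stopf("noiseVar must be positive")
  n <- nrow(A)
  S <- diag(n) + edgeCorr * A
  d <- 0.05
  for (iter in seq_len(60)) {
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev > 1e-8) {
      return(S * noiseVar)
    }
    S <- (S + d * diag(n)) / (1 + d)
    d <- d * 2
  }
  stopf("covariance not positive-definite after maximum diagonal loading")
}

#' Band-limited BOLD-like time series with a prescribed covariance
#'
#' Draws Gaussian series whose cross-covariance follows `cov`, then shapes
#' them so that the shared fluctuations live in the dyadic frequency band
#' of `targetScale` — emulating resting-state data whose covariance is
#' concentrated in the low-frequency interval around 0.032-0.065 Hz. White
#' noise is band-pass filtered in the Fourier domain (the same filter for
#' every region, so cross-correlations are preserved) and mixed through the
#' Cholesky factor of `cov`.
#'
#' @param cov positive-definite covariance matrix.
#' @param nVolumes series length (>= 64; default 400).
#' @param samplingInterval repetition time in seconds (default 2).
#' @param targetScale wavelet level carrying the covariance; default
#'   [selectScale()] of the sampling interval.
#' @param seed integer seed.
#' @param regionLabels optional region names.
#' @return a [RegionalTimeSeries-class].
#' @export
simulateBold <- function(cov, nVolumes = 400, samplingInterval = 2,
                         targetScale = selectScale(samplingInterval),
                         seed = 1L, regionLabels = NULL) {
  stopifnot(is.matrix(cov), nrow(cov) == ncol(cov))
  if (!is_count(nVolumes, 64)) stopf("nVolumes must be an integer >= 64")
  U <- tryCatch(chol(cov), error = function(e) {
    stopf("covariance matrix is not positive-definite")
  })
  p <- nrow(cov)
  if (is.null(regionLabels)) {
    regionLabels <- sprintf("R%03d", seq_len(p))
  }
  band <- c(1 / 2^(targetScale + 1), 1 / 2^targetScale) # cycles/sample
  with_seed(seed, {
    z <- matrix(rnorm(nVolumes * p), nVolumes, p)
    f <- (seq_len(nVolumes) - 1) / nVolumes
    f <- pmin(f, 1 - f) # two-sided frequency axis
    keep <- f >= band[1] & f <= band[2]
    zf <- stats::mvfft(z)
    zf[!keep, ] <- 0
    zb <- Re(stats::mvfft(zf, inverse = TRUE)) / nVolumes
    # renormalise to unit marginal variance before mixing
    zb <- sweep(zb, 2, apply(zb, 2, sd), "/")
    x <- zb %*% U
    new("RegionalTimeSeries",
      data = x, regionLabels = regionLabels,
      samplingInterval = samplingInterval
    )
  })
}

#' Hub disruption of a template network
#'
#' Removes a fraction of the edges incident to the planted hubs, re-attaches
#' a fraction of the removed count between non-hub pairs (the non-hubs
#' gaining connectivity), and repairs connectedness by re-adding the
#' minimum necessary spanning-tree edges of the original template. The
#' resulting edge count relative to the requested budget is reported in the
#' `edgeReport` attribute.
#'
#' @param template a [TemplateNetwork-class].
#' @param strength fraction in \\[0, 1\\] of hub-incident edges removed.
#' @param rewireFraction fraction of removed edges re-attached among
#'   non-hubs (default 1, preserving the edge budget up to repair edges).
#' @param seed integer seed, or NULL to draw from the current RNG state
#'   (used by cohort generators that seed once at the top).
#' @return a [TemplateNetwork-class]; attribute `edgeReport` holds the
#'   target and realised edge counts.
#' @export
applyHubDisruption <- function(template, strength, rewireFraction = 1,
                               seed = 1L) {
  stopifnot(is(template, "TemplateNetwork"))
  if (!is_fraction(strength)) stopf("strength must lie in [0, 1]")
  if (!is_fraction(rewireFraction)) stopf("rewireFraction must lie in [0, 1]")
  run <- function() {
    g <- asIgraph(template)
    n <- igraph::vcount(g)
    hubs <- hubIds(template)
    if (strength == 0) {
      out <- template
      attr(out, "edgeReport") <- list(
        target = igraph::ecount(g), realised = igraph::ecount(g)
      )
      return(out)
    }
    el <- igraph::as_edgelist(g, names = FALSE)
    hub_edges <- which(el[, 1] %in% hubs | el[, 2] %in% hubs)
    k <- round(strength * length(hub_edges))
    drop <- if (k > 0) sample(hub_edges, k) else integer(0)
    g2 <- igraph::delete_edges(g, drop)
    # re-attach among non-hub pairs
    r <- round(rewireFraction * k)
    nonhubs <- setdiff(seq_len(n), hubs)
    if (r > 0 && length(nonhubs) >= 2) {
      A <- igraph::as_adjacency_matrix(g2, sparse = FALSE) > 0
      cand <- all_pairs(length(nonhubs))
      cand <- cbind(nonhubs[cand[, 1]], nonhubs[cand[, 2]])
      open <- which(!A[cand])
      r <- min(r, length(open))
      if (r > 0) {
        pick <- cand[sample(open, r), , drop = FALSE]
        g2 <- igraph::add_edges(g2, t(pick))
      }
    }
    # connectivity repair: re-add original-template spanning-tree edges
    # that bridge the remaining components
    if (!igraph::is_connected(g2)) {
      tree <- igraph::as_edgelist(
        igraph::mst(g, weights = rep(1, igraph::ecount(g))),
        names = FALSE
      )
      for (e in seq_len(nrow(tree))) {
        comp <- igraph::components(g2)$membership
        u <- tree[e, 1]
        v <- tree[e, 2]
        if (comp[u] != comp[v]) {
          g2 <- igraph::add_edges(g2, c(u, v))
          if (igraph::is_connected(g2)) break
        }
      }
    }
    target <- igraph::ecount(g) - k + r
    out <- new("TemplateNetwork",
      graph = g2, hubIds = as.integer(hubs),
      edgeBudget = template@edgeBudget
    )
    attr(out, "edgeReport") <- list(
      target = target, realised = igraph::ecount(g2)
    )
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Motion trace with injected composite-motion spikes
#'
#' Six-column motion trace (3 translations in mm, 3 rotations in radians)
#' of small Gaussian jitter, plus level shifts of `spikeMm` on the first
#' translation at the requested volumes — each shift produces one
#' inter-volume composite displacement above the shift size. A matched
#' global-signal spike train is returned for signal-based flagging tests.
#'
#' @param nVolumes number of volumes.
#' @param spikeTimes integer volume indices (2..nVolumes) receiving spikes.
#' @param spikeMm spike amplitude in millimetres (default 6).
#' @param seed integer seed.
#' @return list with `motion` (nVolumes x 6 matrix) and `globalSpike`
#'   (numeric vector, `spikeMm` at spike volumes, 0 elsewhere).
#' @export
simulateMotionArtifacts <- function(nVolumes, spikeTimes = integer(),
                                    spikeMm = 6, seed = 1L) {
  if (!is_count(nVolumes, 2)) stopf("nVolumes must be an integer >= 2")
  spikeTimes <- as.integer(spikeTimes)
  if (length(spikeTimes) && (min(spikeTimes) < 2 || max(spikeTimes) > nVolumes)) {
    stopf("spikeTimes must lie in 2..nVolumes")
  }
  with_seed(seed, {
    motion <- cbind(
      matrix(rnorm(nVolumes * 3, sd = 0.05), nVolumes, 3),
      matrix(rnorm(nVolumes * 3, sd = 5e-4), nVolumes, 3)
    )
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    sgn <- 1
    for (t in spikeTimes) {
      motion[t:nVolumes, "tx"] <- motion[t:nVolumes, "tx"] + sgn * spikeMm
      sgn <- -sgn
    }
    spike <- numeric(nVolumes)
    spike[spikeTimes] <- spikeMm
    list(motion = motion, globalSpike = spike)
  })
}

#' Longitudinal HDI observations from a known mixed model
#'
#' Draws one HDI value per subject and timepoint from
#' `hdi = intercept + bC * MCS + bT * (time - 1) + bI * MCS * (time - 1)
#' + subject_intercept + noise`, with consciousness coded MCS = 1 / C = 0.
#' The fixed-effect defaults are the clustering-metric coefficients of the
#' study cohort this generator emulates; the dispersions are moderate
#' HDI-scale noise (see the methods vignette).
#'
#' @param nSubjects number of subjects (default 39, the pooled cohort
#'   size: 11 MCS, 28 C).
#' @param intercept,betaConsciousness,betaTime,betaInteraction fixed
#'   effects on the HDI scale.
#' @param sdRandomIntercept between-subject SD (default 0.15).
#' @param sdResidual residual SD (default 0.10).
#' @param fractionMCS fraction of subjects in the MCS state (default
#'   11/39).
#' @param metric metric label written in the table (default "clustering").
#' @param seed integer seed.
#' @return data.frame with columns subject, timepoint, state, hdi_metric,
#'   hdi_value.
#' @export
simulateHdiLongitudinal <- function(nSubjects = 39, intercept = -0.20,
                                    betaConsciousness = -0.24,
                                    betaTime = 0.09,
                                    betaInteraction = -0.16,
                                    sdRandomIntercept = 0.15,
                                    sdResidual = 0.10,
                                    fractionMCS = 11 / 39,
                                    metric = "clustering", seed = 1L) {
  if (!is_count(nSubjects, 2)) stopf("nSubjects must be an integer >= 2")
  if (sdRandomIntercept < 0 || sdResidual < 0) {
    stopf("dispersions must be non-negative")
  }
  with_seed(seed, {
    nMCS <- round(fractionMCS * nSubjects)
    state <- rep(c("MCS", "C"), c(nMCS, nSubjects - nMCS))
    b <- rnorm(nSubjects, sd = sdRandomIntercept)
    rows <- expand.grid(
      subject = seq_len(nSubjects), timepoint = c(1L, 2L),
      KEEP.OUT.ATTRS = FALSE
    )
    mcs <- as.numeric(state[rows$subject] == "MCS")
    tt <- rows$timepoint - 1
    mu <- intercept + betaConsciousness * mcs + betaTime * tt +
      betaInteraction * mcs * tt
    hdi <- mu + b[rows$subject] + rnorm(nrow(rows), sd = sdResidual)
    data.frame(
      subject = sprintf("S%03d", rows$subject),
      timepoint = rows$timepoint,
      state = state[rows$subject],
      hdi_metric = metric,
      hdi_value = hdi,
      stringsAsFactors = FALSE
    )
  })
}

#' Cohort of individual graphs at group-specific disruption strengths
#'
#' Generates one graph per subject: the healthy group keeps the template
#' (strength 0 by default), patient groups receive hub disruption at their
#' group strength, each subject with its own random draw. Group sizes and
#' strengths default to the emulated study structure (20 HS, 9 MCS at
#' strength 0.5, 15 C at strength 0.2).
#'
#' @param template a [TemplateNetwork-class].
#' @param sizes named integer vector of group sizes.
#' @param strengths named numeric vector of disruption strengths, same
#'   names as `sizes`.
#' @param rewireFraction passed to [applyHubDisruption()].
#' @param seed integer seed.
#' @return named list subject id -> [TemplateNetwork-class]; names carry
#'   the group as prefix ("HS01", "MCS03", ...).
#' @export
simulateGraphCohort <- function(template,
                                sizes = c(HS = 20, MCS = 9, C = 15),
                                strengths = c(HS = 0, MCS = 0.5, C = 0.2),
                                rewireFraction = 1, seed = 1L) {
  stopifnot(is(template, "TemplateNetwork"))
  if (!all(names(sizes) %in% names(strengths))) {
    stopf("every group in sizes needs a strength")
  }
  with_seed(seed, {
    out <- list()
    for (grp in names(sizes)) {
      for (i in seq_len(sizes[[grp]])) {
        sid <- sprintf("%s%02d", grp, i)
        out[[sid]] <- applyHubDisruption(
          template, strengths[[grp]],
          rewireFraction = rewireFraction, seed = NULL
        )
      }
    }
    out
  })
}
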