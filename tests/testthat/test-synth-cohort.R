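# Synthetic cohort generators: template topology, covariance construction,
# BOLD simulation, hub disruption, motion artifacts, longitudinal tables.

test_that("template graph honours node count, edge budget, connectivity and hub ranking", {
  cases <- list(
    list(n = 107, h = 10, e = 283, seed = 1),
    list(n = 5, h = 1, e = 4, seed = 0),
    list(n = 20, h = 3, e = 40, seed = 7)
  )
  for (cs in cases) {
    tpl <- makeTemplateGraph(cs$n, cs$h, cs$e, seed = cs$seed)
    g <- asIgraph(tpl)
    expect_equal(igraph::vcount(g), cs$n)
    expect_equal(igraph::ecount(g), cs$e)
    expect_true(igraph::is_connected(g))
    deg <- metricValues(degreeProfile(tpl))
    hubs <- hubIds(tpl)
    expect_true(min(deg[hubs]) > max(deg[-hubs]))
  }
})

test_that("a spanning-tree budget yields a tree whose hub is the max-degree node", {
  tpl <- makeTemplateGraph(5, 1, 4, seed = 0)
  expect_equal(edgeCount(tpl), 4L) # n - 1: a tree
  deg <- metricValues(degreeProfile(tpl))
  expect_equal(which.max(deg), hubIds(tpl))
})

test_that("planted hub degrees clear the 90th percentile of non-hub degrees", {
  tpl <- makeTemplateGraph(20, 3, 40, seed = 7)
  deg <- metricValues(degreeProfile(tpl))
  expect_true(min(deg[hubIds(tpl)]) >
    quantile(deg[-hubIds(tpl)], 0.9))
})

test_that("infeasible edge budgets raise parameter errors", {
  expect_error(makeTemplateGraph(10, 2, 8, seed = 1), "infeasible")
  expect_error(makeTemplateGraph(10, 2, 50, seed = 1), "infeasible")
  expect_error(makeTemplateGraph(10, 10, 20, seed = 1), "nHubs")
})

test_that("graph covariance is positive-definite, unit-variance-scaled and edge-ordered", {
  # edgeless adjacency: independence -> identity covariance
  cv0 <- graphToCovariance(matrix(0, 3, 3), edgeCorr = 0.5)
  expect_equal(cv0, diag(3))
  # 2-node single edge at 0.5 stays exactly 0.5 (already PD)
  pair <- new("TemplateNetwork",
    graph = igraph::graph_from_edgelist(rbind(c(1, 2)), directed = FALSE),
    hubIds = 1L, edgeBudget = 1L
  )
  cv2 <- graphToCovariance(pair, edgeCorr = 0.5)
  expect_equal(cv2[1, 2], 0.5)
  expect_equal(diag(cv2), rep(1, 2))

  tpl <- makeTemplateGraph(10, 2, 15, seed = 3)
  cv <- graphToCovariance(tpl, edgeCorr = 0.4)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 1e-8)
  A <- as.matrix(igraph::as_adjacency_matrix(asIgraph(tpl)))
  up <- upper.tri(cv)
  expect_gt(mean(cv[A > 0 & up]), mean(cv[A == 0 & up]))
})

test_that("covariance generator is PD across many templates", {
  for (seed in 1:20) {
    tpl <- makeTemplateGraph(30, 4, 60, seed = seed)
    cv <- graphToCovariance(tpl, edgeCorr = 0.5)
    expect_gt(min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values), 1e-8)
  }
})

test_that("simulated BOLD is deterministic and recovers planted correlations at the target scale", {
  a <- simulateBold(diag(4), nVolumes = 128, seed = 9)
  b <- simulateBold(diag(4), nVolumes = 128, seed = 9)
  expect_identical(tsMatrix(a), tsMatrix(b))

  cv <- diag(3)
  cv[1, 2] <- cv[2, 1] <- 0.8
  ts <- simulateBold(cv, nVolumes = 400, samplingInterval = 2, seed = 4)
  cm <- corMatrix(waveletCorrelationMatrix(ts, level = 3))
  expect_gt(cm[1, 2], 0.5)

  expect_error(simulateBold(matrix(c(1, 2, 2, 1), 2), 128), "positive-definite")
})

test_that("independent regions show near-zero wavelet correlation on average", {
  vals <- sapply(1:20, function(s) {
    ts <- simulateBold(diag(6), nVolumes = 400, seed = s)
    m <- corMatrix(waveletCorrelationMatrix(ts, level = 3))
    mean(m[upper.tri(m)])
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("BOLD sample covariance error shrinks as the series lengthens", {
  tpl <- makeTemplateGraph(8, 2, 12, seed = 5)
  cv <- graphToCovariance(tpl, edgeCorr = 0.4)
  frob <- function(n) {
    errs <- sapply(1:8, function(s) {
      ts <- simulateBold(cv, nVolumes = n, seed = s)
      cm <- corMatrix(waveletCorrelationMatrix(ts, level = 3))
      sqrt(sum((cm - cov2cor(cv))^2))
    })
    mean(errs)
  }
  e1 <- frob(128)
  e2 <- frob(512)
  expect_lt(e2, e1 * 0.75) # halving expected at 4x length, with slack
})

test_that("hub disruption at strength 0 is the identity", {
  tpl <- makeTemplateGraph(20, 3, 40, seed = 2)
  out <- applyHubDisruption(tpl, 0, seed = 10)
  expect_true(igraph::identical_graphs(asIgraph(out), asIgraph(tpl)))
})

test_that("full disruption of a star drops the center to the repair minimum", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  tpl <- new("TemplateNetwork", graph = star, hubIds = 1L, edgeBudget = 5L)
  out <- applyHubDisruption(tpl, 1, rewireFraction = 1, seed = 3)
  g <- asIgraph(out)
  expect_true(igraph::is_connected(g))
  expect_equal(unname(igraph::degree(g)[1]), 1) # one repair edge only
})

test_that("mean hub degree decreases monotonically in disruption strength", {
  tpl <- makeTemplateGraph(107, 10, 283, seed = 1)
  hubs <- hubIds(tpl)
  grid <- c(0, 0.2, 0.4, 0.6)
  means <- sapply(grid, function(s) {
    mean(sapply(1:20, function(seed) {
      d <- applyHubDisruption(tpl, s, seed = seed)
      mean(metricValues(degreeProfile(d))[hubs])
    }))
  })
  expect_true(all(diff(means) < 0))
})

test_that("disruption preserves the edge budget within 1% when rewiring fully", {
  tpl <- makeTemplateGraph(107, 10, 283, seed = 1)
  for (s in c(0.2, 0.5)) {
    out <- applyHubDisruption(tpl, s, rewireFraction = 1, seed = 8)
    rep <- attr(out, "edgeReport")
    expect_lte(abs(rep$realised - 283) / 283, 0.01)
  }
})

test_that("motion traces stay sub-millimetre without spikes and spike where asked", {
  art <- simulateMotionArtifacts(100, seed = 1)
  expect_lt(max(compositeMotion(art$motion)), 1)

  art2 <- simulateMotionArtifacts(100, spikeTimes = 50L, spikeMm = 6, seed = 1)
  cmv <- compositeMotion(art2$motion)
  expect_gt(cmv[50], 5)
  expect_equal(which(cmv > 5), 50L)
  expect_equal(which(art2$globalSpike != 0), 50L)
})

test_that("longitudinal HDI generator honours the degenerate and seeded contracts", {
  flat <- simulateHdiLongitudinal(
    nSubjects = 10, intercept = -0.2,
    betaConsciousness = 0, betaTime = 0, betaInteraction = 0,
    sdRandomIntercept = 0, sdResidual = 0, seed = 1
  )
  expect_equal(flat$hdi_value, rep(-0.2, nrow(flat)))

  a <- simulateHdiLongitudinal(nSubjects = 30, seed = 7)
  b <- simulateHdiLongitudinal(nSubjects = 30, seed = 7)
  expect_identical(a, b)
  expect_setequal(unique(a$state), c("MCS", "C"))
  expect_equal(nrow(a), 60) # two timepoints per subject
})

test_that("graph cohorts are reproducible and group-structured", {
  tpl <- makeTemplateGraph(40, 5, 90, seed = 2)
  c1 <- simulateGraphCohort(tpl, sizes = c(HS = 4, MCS = 3, C = 3), seed = 5)
  c2 <- simulateGraphCohort(tpl, sizes = c(HS = 4, MCS = 3, C = 3), seed = 5)
  expect_identical(names(c1), names(c2))
  for (sid in names(c1)) {
    expect_true(igraph::identical_graphs(asIgraph(c1[[sid]]), asIgraph(c2[[sid]])))
  }
  expect_length(c1, 10)
})
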