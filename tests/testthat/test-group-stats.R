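# Rank tests against enumeration oracles, the mixed model, nodal
# exploration.

test_that("Mann-Whitney matches its enumeration oracle and the hand cases", {
  expect_equal(mannWhitney(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(mannWhitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  set.seed(1)
  for (rep in 1:20) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    vals <- sample(1000, n1 + n2) / 10 # untied
    a <- vals[seq_len(n1)]
    b <- vals[-seq_len(n1)]
    expect_equal(mannWhitney(a, b)$p, oracle_mann_whitney_p(a, b),
      tolerance = 1e-12
    )
  }
  expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
})

test_that("Kruskal-Wallis matches rank-sum hand computation and degenerates to p = 1", {
  # groups {1,2}, {3,4}, {5,6}: ranks are the values themselves
  # H = 12/(n(n+1)) * sum n_i (Rbar_i - Rbar)^2 = 12/42 * (2*(1.5-3.5)^2 +
  #     2*(3.5-3.5)^2 + 2*(5.5-3.5)^2) = 12/42 * 16 = 32/7
  k <- kruskalWallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(unname(k$statistic), 32 / 7)
  expect_equal(k$p, pchisq(32 / 7, df = 2, lower.tail = FALSE))

  expect_warning(k0 <- kruskalWallis(list(c(2, 2), c(2, 2))), "degenerate")
  expect_equal(k0$p, 1)
  expect_equal(unname(k0$statistic), 0)
  expect_error(kruskalWallis(list(1:3)), "at least 2")
})

test_that("two-group Kruskal-Wallis agrees asymptotically with Mann-Whitney", {
  set.seed(2)
  a <- rnorm(30)
  b <- rnorm(30, 0.8)
  kw <- kruskalWallis(list(a, b))
  mw <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
  # H = z^2 for two untied groups, so the chi-square and normal p agree
  expect_equal(kw$p, mw$p.value, tolerance = 1e-10)
})

test_that("Wilcoxon signed-rank matches its sign-pattern enumeration oracle", {
  x1 <- c(1, 2, 3, 4, 5, 6)
  # all six differences positive (and untied): the most extreme of the 2^6
  # sign patterns on either side
  expect_equal(wilcoxonSignedRank(x1 + x1 / 10, x1)$p, 2 / 2^6)
  expect_warning(w0 <- wilcoxonSignedRank(x1, x1), "zero")
  expect_equal(w0$p, 1)
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    x <- sample(1000, n) / 10
    y <- x + sample(c(-1, 1), n, replace = TRUE) * sample(100, n) / 100
    expect_equal(wilcoxonSignedRank(x, y)$p, oracle_signed_rank_p(x, y),
      tolerance = 1e-12
    )
  }
  expect_error(wilcoxonSignedRank(1:3, 1:4), "equal length")
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisherExact(matrix(c(5, 5, 5, 5), 2))$p, 1)
  expect_equal(fisherExact(matrix(c(3, 0, 0, 3), 2))$p, 0.1)
  expect_equal(fisherExact(matrix(c(0, 0, 4, 5), 2))$p, 1) # zero margin
  set.seed(4)
  for (rep in 1:30) {
    tab <- matrix(rpois(4, 3), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisherExact(tab)$p, oracle_fisher_p(tab), tolerance = 1e-9)
  }
  expect_error(fisherExact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("the mixed model is exact under zero dispersion and reproducible", {
  flat <- simulateHdiLongitudinal(
    nSubjects = 12, intercept = -0.2,
    betaConsciousness = 0, betaTime = 0, betaInteraction = 0,
    sdRandomIntercept = 0, sdResidual = 0, seed = 1
  )
  fit <- suppressWarnings(suppressMessages(
    fitHdiMixedModel(flat, nBoot = 50, seed = 2, bootEngine = "ols")
  ))
  cf <- fit@coefficients
  expect_equal(cf$estimate[cf$term == "intercept"], -0.2, tolerance = 1e-8)
  expect_equal(cf$estimate[cf$term != "intercept"], rep(0, 3), tolerance = 1e-8)

  d <- simulateHdiLongitudinal(nSubjects = 24, seed = 5)
  f1 <- fitHdiMixedModel(d, nBoot = 60, seed = 9, bootEngine = "ols")
  f2 <- fitHdiMixedModel(d, nBoot = 60, seed = 9, bootEngine = "ols")
  expect_identical(f1@coefficients, f2@coefficients)
})

test_that("bootstrap CIs contain the estimate and lmer/ols engines agree on balanced data", {
  d <- simulateHdiLongitudinal(nSubjects = 30, seed = 7)
  fit <- fitHdiMixedModel(d, nBoot = 80, seed = 3, bootEngine = "lmer")
  cf <- fit@coefficients
  expect_true(all(cf$ci_low <= cf$estimate & cf$estimate <= cf$ci_high))
  expect_true(all(cf$p_value >= 0 & cf$p_value <= 1))
  expect_equal(fit@randomInterceptSD >= 0, TRUE)

  # on the balanced design the OLS coefficients equal the GLS/lmer ones
  df <- data.frame(
    subject = d$subject, mcs = as.numeric(d$state == "MCS"),
    time01 = d$timepoint - 1, y = d$hdi_value
  )
  ols <- hdinet:::.fit_coefs(df, "ols")
  mer <- hdinet:::.fit_coefs(df, "lmer")
  expect_equal(unname(ols), unname(mer), tolerance = 1e-6)
})

test_that("single-state data reduce the model with a warning", {
  d <- simulateHdiLongitudinal(nSubjects = 10, fractionMCS = 0, seed = 2)
  expect_warning(
    fit <- suppressMessages(fitHdiMixedModel(d, nBoot = 30, seed = 1, bootEngine = "ols")),
    "one consciousness state"
  )
  cf <- fit@coefficients
  expect_true(all(is.na(cf$estimate[cf$term %in% c("consciousness", "consciousness:time")])))
  expect_false(is.na(cf$estimate[cf$term == "intercept"]))
})

test_that("nodal exploration flags a planted shift and respects BH monotonicity", {
  set.seed(6)
  nA <- 15
  nB <- 15
  n_nodes <- 107
  a <- matrix(rnorm(nA * n_nodes), nA)
  b <- matrix(rnorm(nB * n_nodes), nB)
  b[, 42] <- b[, 42] + 3 # 3 SD shift at one node
  res <- nodalExploration(a, b)
  expect_equal(which.min(res$p_adjusted), 42L)
  o <- order(res$p_raw)
  expect_true(all(diff(res$p_adjusted[o]) >= -1e-12))

  same <- nodalExploration(a, a + 0) # identical groups
  expect_true(all(same$p_adjusted > 0.05))

  bf <- nodalExploration(a, b, correction = "bonferroni")
  expect_equal(bf$p_adjusted, pmin(1, bf$p_raw * n_nodes))
  expect_error(nodalExploration(a[1, , drop = FALSE], b), "2 members")
})
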