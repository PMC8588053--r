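test_that("sample moments use uncorrected central-moment estimators", {
  expect_equal(sample_moments(c(-1, 0, 1))$skewness, 0)
  m <- sample_moments(c(0, 0, 0, 1))
  o <- oracle_moments(c(0, 0, 0, 1))
  expect_equal(m$skewness, o$skewness) # 2/sqrt(3)
  expect_equal(m$kurtosis, o$kurtosis) # 7/3
  expect_equal(m$skewness, 2 / sqrt(3))
  expect_equal(m$kurtosis, 7 / 3)
  # moment inequality kurtosis >= 1 + skewness^2 on arbitrary data
  set.seed(4)
  for (i in 1:20) {
    mm <- sample_moments(rgamma(25, shape = runif(1, 0.3, 5)))
    expect_gte(mm$kurtosis, 1 + mm$skewness^2)
  }
  expect_error(sample_moments(3), "two values")
  expect_error(sample_moments(c(2, 2, 2)), "variance")
})

test_that("large Gamma samples recover the closed-form skewness 2/sqrt(a)", {
  set.seed(9)
  x <- rgamma(1e6, shape = 0.6, scale = 10)
  expect_lt(abs(sample_moments(x)$skewness / (2 / sqrt(0.6)) - 1), 0.03)
})

test_that("Jarque-Bera statistic matches the printed fluid-mode values", {
  ms <- function(n, b1, b2) {
    structure(list(n = n, mean = NA_real_, skewness = b1, kurtosis = b2),
              class = "moment_summary")
  }
  expect_equal(round(jarque_bera(ms(304, 2.307, 9.048))$statistic), 733)
  expect_equal(round(jarque_bera(ms(304, 4.776, 39.379))$statistic), 17919)
  # Gaussian moments give exactly zero
  expect_equal(jarque_bera(ms(100, 0, 3))$statistic, 0)
  # JB is always non-negative
  set.seed(11)
  for (i in 1:20) {
    expect_gte(jarque_bera(rnorm(40))$statistic, 0)
  }
})

test_that("Monte-Carlo JB critical values sit below the asymptote and are reproducible", {
  c60 <- jb_critical(60, replicates = 2e4, seed = 3)
  expect_gt(c60, 4.7)
  expect_lt(c60, 5.5)
  expect_lt(c60, qchisq(0.95, 2))
  expect_equal(jb_critical(60, replicates = 2e4, seed = 3), c60)
  expect_error(jb_critical(4), "at least 8")
  expect_error(jb_critical(60, replicates = 100), "replicates")
})

test_that("Kruskal-Wallis wrapper matches hand-computed H and handles degeneracy", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 27/7
  expect_equal(kw$h_statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(kw$p_value, pchisq(27 / 7, 1, lower.tail = FALSE))
  expect_equal(kw$dof, 1)
  expect_equal(kruskal_wallis(list(c(1, 2), c(1, 2)))$h_statistic, 0)
  all_tied <- kruskal_wallis(list(c(5, 5), c(5, 5, 5)))
  expect_equal(all_tied$h_statistic, 0)
  expect_equal(all_tied$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(21)
  g1 <- rgamma(15, 2); g2 <- rgamma(12, 3); g3 <- rgamma(10, 2.5)
  base <- kruskal_wallis(list(g1, g2, g3))
  for (f in list(log, sqrt, function(z) z^3, function(z) exp(z / 5))) {
    tr <- kruskal_wallis(lapply(list(g1, g2, g3), f))
    expect_equal(tr$h_statistic, base$h_statistic)
    expect_equal(tr$p_value, base$p_value)
  }
})

test_that("Gamma MLE recovers parameters and beats the moment start", {
  set.seed(14)
  x <- rgamma(5e4, shape = 0.75, scale = 12.6)
  fit <- gamma_fit_mle(x)
  expect_lt(abs(fit$shape / 0.75 - 1), 0.03)
  expect_lt(abs(fit$scale / 12.6 - 1), 0.03)
  # exponential special case: shape ~ 1
  set.seed(15)
  e <- rgamma(2e4, shape = 1, scale = 3)
  expect_lt(abs(gamma_fit_mle(e)$shape - 1), 0.05)
  # the MLE log-likelihood dominates the method-of-moments fit
  set.seed(16)
  for (i in 1:5) {
    z <- rgamma(500, shape = runif(1, 0.4, 4), scale = runif(1, 1, 20))
    fit <- gamma_fit_mle(z)
    a_mom <- mean(z)^2 / mean((z - mean(z))^2)
    ll <- function(a, b) sum(dgamma(z, shape = a, scale = b, log = TRUE))
    expect_gte(attr(fit, "loglik"), ll(a_mom, mean(z) / a_mom))
  }
  expect_error(gamma_fit_mle(c(1, -1, rep(2, 10))), "positive")
  expect_error(gamma_fit_mle(rep(3, 12)), "variance|degenerate")
})

test_that("Gamma MLE agrees with an independent fitting routine", {
  set.seed(17)
  x <- rgamma(2000, shape = 1.8, scale = 4.2)
  fit <- gamma_fit_mle(x)
  ref <- fitdistrplus::fitdist(x, "gamma")
  # fitdistrplus optimizes numerically; agreement to ~0.1% is its precision
  expect_equal(fit$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(1 / fit$scale, unname(ref$estimate["rate"]), tolerance = 1e-3)
})

test_that("moment inversion maps (mean, skewness) to Gamma shape/scale", {
  g <- gamma_fit_moments(9.45, 2.314)
  expect_equal(g$shape, (2 / 2.314)^2)
  expect_equal(g$scale, 9.45 / g$shape)
  expect_equal(gamma_fit_moments(5, 2)$shape, 1)
  # round trip through the Gamma moment identities
  g2 <- gamma_params(3.7, 2.2)
  back <- gamma_fit_moments(g2$shape * g2$scale, 2 / sqrt(g2$shape))
  expect_equal(back$shape, g2$shape)
  expect_equal(back$scale, g2$scale)
  expect_error(gamma_fit_moments(5, -1), "skewness")
  expect_error(gamma_fit_moments(-5, 1), "mean")
})

test_that("fitted Gamma skewness tracks the sample skewness", {
  set.seed(18)
  for (a_true in c(0.6, 2, 6)) {
    x <- rgamma(2e4, shape = a_true, scale = 5)
    fit <- gamma_fit_mle(x)
    expect_lt(abs(2 / sqrt(fit$shape) - sample_moments(x)$skewness) /
                (2 / sqrt(a_true)), 0.15)
  }
})

test_that("discrimination test takes the non-parametric branch for skewed data", {
  set.seed(31)
  a <- rgamma(304, shape = 0.7, scale = 12)
  b <- rgamma(304, shape = 0.6, scale = 25)
  res <- pairwise_discrimination(a, b, jb_critical_value = c(5.7, 5.7))
  expect_equal(res$branch, "nonparametric")
  expect_true(is.na(res$levene_p))
  # identical samples cannot be distinguished
  same <- pairwise_discrimination(a, a)
  expect_false(same$reject)
  expect_equal(same$p_value, 1, tolerance = 1e-9)
})

test_that("discrimination test goes parametric on Gaussian data and is calibrated", {
  branch <- character(60)
  p <- numeric(60)
  for (s in 1:60) {
    set.seed(400 + s)
    a <- rnorm(50, 10, 2)
    b <- rnorm(50, 10, 2)
    res <- pairwise_discrimination(a, b)
    branch[s] <- res$branch
    p[s] <- res$p_value
  }
  # JB passes Gaussian data at rate ~0.95 per sample
  expect_gte(mean(branch == "parametric"), 0.8)
  # under the null, rejections stay near the nominal 5%
  expect_lte(mean(p < 0.05), 0.15)
  expect_gte(mean(p > 0.2), 0.5)
})
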