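test_that("Newton logistic fit matches the brute-force grid oracle on a toy set", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(0, 0, 1, 0, 1, 1)
  fit <- fit_logistic(x, y)
  oracle <- oracle_grid_logistic(x, y)
  expect_equal(fit$beta0, oracle$beta0, tolerance = 5e-4)
  expect_equal(fit$beta1, oracle$beta1, tolerance = 5e-4)
  expect_gte(fit$loglik, oracle$loglik - 1e-6)
  expect_lt(fit$gradient_norm, 1e-8)
  expect_true(fit$converged)
})

test_that("logistic fit agrees with glm and is convergent on random data", {
  set.seed(51)
  for (i in 1:5) {
    x <- c(rgamma(40, 2, rate = 0.4), rgamma(40, 5, rate = 0.4))
    y <- rep(c(0, 1), each = 40)
    fit <- fit_logistic(x, y)
    ref <- stats::glm(y ~ x, family = stats::binomial())
    expect_equal(fit$beta0, unname(coef(ref)[1]), tolerance = 1e-6)
    expect_equal(fit$beta1, unname(coef(ref)[2]), tolerance = 1e-6)
    expect_gt(fit$beta1, 0) # positive class has larger radii
  }
})

test_that("permuted labels give a null slope", {
  set.seed(52)
  x <- rgamma(200, 3, rate = 0.3)
  y <- sample(rep(c(0, 1), each = 100))
  fit <- fit_logistic(x, y)
  expect_lt(abs(fit$beta1), 3 * fit$se[2])
})

test_that("separated data are flagged and capped rather than diverging", {
  x <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_warning(fit <- fit_logistic(x, y), "separation")
  expect_true(fit$separated)
  expect_lte(max(abs(c(fit$beta0, fit$beta1))), 50)
  # capped fit still ranks the classes correctly
  expect_gt(min(predict(fit, c(10, 11, 12))),
            max(predict(fit, c(1, 2, 3))))
  expect_error(fit_logistic(x, rep(1, 6)), "both classes")
})

test_that("ROC endpoints, degenerate scores and label swaps behave canonically", {
  r <- roc_curve(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$youden, 0.5) # halved convention: perfect = 0.5
  pts <- r$points
  expect_true(any(pts$sensitivity == 0 & pts$specificity == 1))
  expect_true(any(pts$sensitivity == 1 & pts$specificity == 0))
  # constant scores carry no information
  expect_equal(roc_curve(rep(2, 10), rep(c(0, 1), 5))$auc, 0.5)
  # reversing the scores anti-classifies
  expect_equal(roc_curve(-c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))$auc, 0)
  # swapping labels maps AUC to 1 - AUC
  set.seed(61)
  s <- rnorm(30); lab <- rep(c(0, 1), 15)
  expect_equal(roc_curve(s, lab)$auc, 1 - roc_curve(s, 1 - lab)$auc)
})

test_that("trapezoidal AUC equals the midrank Mann-Whitney statistic", {
  set.seed(62)
  for (i in 1:50) {
    n1 <- sample(5:25, 1); n0 <- sample(5:25, 1)
    s <- round(c(rnorm(n0), rnorm(n1, mean = runif(1, 0, 2))), 1) # ties
    lab <- rep(c(0, 1), c(n0, n1))
    expect_equal(roc_curve(s, lab)$auc, oracle_mw_auc(s, lab),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(63)
  s <- c(rnorm(40), rnorm(40, 1)); lab <- rep(c(0, 1), each = 40)
  r <- roc_curve(s, lab)
  ref <- pROC::roc(lab, s, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("ROC is invariant under the monotone logistic link", {
  set.seed(64)
  x <- c(rgamma(30, 2), rgamma(30, 4))
  lab <- rep(c(0, 1), each = 30)
  r_raw <- roc_curve(x, lab)
  r_link <- roc_curve(plogis(-2 + 0.8 * x), lab)
  expect_equal(r_raw$auc, r_link$auc, tolerance = 1e-12)
  expect_equal(r_raw$points$sensitivity, r_link$points$sensitivity)
})

test_that("Youden index matches exhaustive cutoff enumeration", {
  set.seed(65)
  for (i in 1:20) {
    s <- round(rnorm(8), 1)
    lab <- sample(rep(c(0, 1), 4))
    r <- roc_curve(s, lab)
    expect_equal(r$youden, oracle_youden(s, lab), tolerance = 1e-12)
    expect_equal(youden(r, halved = FALSE)$youden,
                 oracle_youden(s, lab, halved = FALSE), tolerance = 1e-12)
    # halved Youden lives in [0, 0.5]
    expect_gte(r$youden, 0)
    expect_lte(r$youden, 0.5)
  }
  # no-skill scores: Se + Sp = 1 everywhere
  expect_equal(roc_curve(rep(1, 6), c(0, 1, 0, 1, 0, 1))$youden, 0)
})

test_that("confusion counts and accuracy follow the cutoff rule", {
  s <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.6, 0.2)
  lab <- c(1, 1, 1, 1, 0, 0, 0)
  m <- accuracy_at_cutoff(s, lab, 0.5)
  expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(3, 2, 1, 1))
  expect_equal(m$accuracy, 5 / 7)
  expect_equal(m$n_total, 7)
  # cutoff below every score calls everything positive
  expect_equal(accuracy_at_cutoff(s, lab, -Inf)$accuracy, mean(lab == 1))
  expect_equal(accuracy_at_cutoff(s, lab, Inf)$accuracy, mean(lab == 0))
  expect_error(accuracy_at_cutoff(numeric(0), logical(0), 0.5),
               "no observations")
})

test_that("AUC categories follow the three-level scale with upward ties", {
  expect_equal(auc_category(c(0.852, 0.762, 0.579)),
               c("high", "medium", "low"))
  expect_equal(auc_category(0.8), "high")
  expect_equal(auc_category(0.7), "medium")
  expect_equal(auc_category(0.699), "low")
  expect_error(auc_category(1.2), "\\[0, 1\\]")
})

test_that("hold-out split is stratified, disjoint, exhaustive and reproducible", {
  lab <- rep(c(0, 1), each = 60)
  sp <- holdout_split(lab, 0.8, seed = 10)
  expect_equal(length(sp$eval), 96) # 48 per class
  expect_equal(length(sp$train), 24)
  expect_equal(sum(lab[sp$eval]), 48)
  expect_equal(sum(lab[sp$train]), 12)
  expect_equal(sort(c(sp$eval, sp$train)), seq_along(lab))
  expect_length(intersect(sp$eval, sp$train), 0)
  expect_identical(holdout_split(lab, 0.8, seed = 10), sp)
  # round-half-to-even: 0.5 * 3 = 1.5 -> 2 eval per class
  sp3 <- holdout_split(rep(c(0, 1), each = 3), 0.5, seed = 1)
  expect_equal(length(sp3$eval), 4)
  expect_equal(length(sp3$train), 2)
  expect_error(holdout_split(rep(c(0, 1), each = 2), 0.9, seed = 1),
               "empty partition")
})
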