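test_that("Monte-Carlo dataset generation honours sizes, moments and seeding", {
  cfg <- pair_config(gamma_params(2, 3), gamma_params(4, 3), n_a = 60,
                     n_b = 40, n_datasets = 10, seed = 5)
  sets <- generate_mc_datasets(cfg)
  expect_length(sets, 10)
  for (d in sets) {
    expect_length(d$values, 100)
    expect_equal(sum(d$labels), 40)
    expect_true(all(d$values > 0))
  }
  # same master seed -> bit-identical datasets
  expect_identical(generate_mc_datasets(cfg), sets)
  # pooled draws match the Gamma mean a*b within 1%
  big <- pair_config(gamma_params(2, 3), gamma_params(4, 3), n_a = 5e4,
                     n_b = 10, n_datasets = 2, seed = 6)
  pooled <- unlist(lapply(generate_mc_datasets(big),
                          function(d) d$values[!d$labels]))
  expect_lt(abs(mean(pooled) / 6 - 1), 0.01)
})

test_that("exchangeable classes give chance-level AUC, separated classes near-perfect", {
  g <- gamma_params(16, 0.5)
  same <- run_pair_classification(pair_config(g, g, n_a = 60, seed = 11))
  expect_lt(abs(same$summary$auc_mean - 0.5), 0.1)
  # means 8 vs 40 at sd 2 and 10: ~10 pooled SDs apart
  far <- run_pair_classification(
    pair_config(gamma_params(16, 0.5), gamma_params(16, 2.5), n_a = 60,
                seed = 12))
  expect_gt(far$summary$auc_mean, 0.99)
})

test_that("replicate mean AUC tracks the distributional P(X_B > X_A) oracle", {
  ga <- gamma_params(4, 1.5) # mean 6
  gb <- gamma_params(4, 2.25) # mean 9
  cfg <- pair_config(ga, gb, n_a = 304, n_datasets = 20, seed = 13)
  res <- run_pair_classification(cfg)
  set.seed(14)
  p_true <- mean(rgamma(1e6, 4, scale = 2.25) > rgamma(1e6, 4, scale = 1.5))
  expect_lt(abs(res$summary$auc_mean - p_true), 0.03)
})

test_that("replicate aggregates are reproducible and well-formed", {
  cfg <- separated_pair(seed = 21)
  r1 <- run_pair_classification(cfg)
  r2 <- run_pair_classification(cfg)
  expect_identical(r1$summary, r2$summary)
  expect_equal(nrow(r1$replicates), 10)
  s <- r1$summary
  expect_true(all(c(s$auc_sd, s$acc_sd, s$youden_sd) >= 0))
  expect_true(s$auc_mean >= 0 && s$auc_mean <= 1)
  expect_true(s$youden_mean >= 0 && s$youden_mean <= 0.5)
  # train on 20%: per class 12 train / 48 eval at n = 60
  expect_true(all(r1$replicates$n_train == 24))
  expect_true(all(r1$replicates$n_eval == 96))
})

test_that("AUC spread is an order of magnitude below the mean for separated classes", {
  ok <- logical(50)
  for (s in 1:50) {
    res <- run_pair_classification(separated_pair(seed = 100 + s))
    ok[s] <- res$summary$auc_sd * 10 < res$summary$auc_mean
  }
  expect_gte(mean(ok), 0.8)
})

test_that("mean AUC increases with class separation", {
  aucs <- sapply(c(1.0, 1.5, 2.5), function(sc) {
    cfg <- pair_config(gamma_params(16, 0.5), gamma_params(16, 0.5 * sc),
                       n_a = 60, n_datasets = 20, seed = 31)
    run_pair_classification(cfg)$summary$auc_mean
  })
  expect_equal(aucs, sort(aucs))
  expect_equal(aucs[1], 0.5, tolerance = 0.1)
})

test_that("test-size sweep reproduces the 34:8 split and skips impossible fractions", {
  cfg <- separated_pair(seed = 41)
  sw <- sweep_test_size(cfg, fractions = c(0.02, 0.1, 0.7, 1.0))
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 4)
  # fraction 0.7 of n = 60: 42 per class, split 34 eval : 8 train
  row <- sw[sw$fraction == 0.7, ]
  expect_equal(row$n_a, 42L)
  expect_equal(row$n_eval_a, 34L)
  expect_equal(row$n_train_a, 8L)
  expect_true(row$valid)
  # fraction 0.02 of 60 -> one pore per class: cannot be split
  expect_false(sw$valid[sw$fraction == 0.02])
  expect_true(all(sw$valid[sw$fraction >= 0.1]))
  # full sweep returns one row per requested fraction
  full <- sweep_test_size(separated_pair(seed = 42))
  expect_equal(nrow(full), 10)
  expect_equal(full$fraction, seq(0.1, 1, by = 0.1))
})

test_that("sweep results for a fraction do not depend on the other fractions", {
  cfg <- separated_pair(seed = 43)
  a <- sweep_test_size(cfg, fractions = c(0.5, 0.7))
  b <- sweep_test_size(cfg, fractions = c(0.5, 0.9))
  expect_equal(a[a$fraction == 0.5, ], b[b$fraction == 0.5, ])
})

test_that("optimal-fraction selection applies the plateau and floor rules", {
  sw <- data.frame(
    fraction = seq(0.1, 0.6, by = 0.1),
    auc_mean = c(0.60, 0.70, 0.78, 0.83, 0.835, 0.84),
    auc_sd = rep(0.05, 6)
  )
  expect_equal(select_optimal_fraction(sw), 0.4)
  # floor never met -> none
  low <- transform(sw, auc_mean = auc_mean - 0.2)
  expect_true(is.na(select_optimal_fraction(low)))
  # steep ramp everywhere: only the last fraction qualifies (vacuous slope)
  ramp <- data.frame(fraction = seq(0.2, 1, by = 0.2),
                     auc_mean = c(0.4, 0.55, 0.7, 0.85, 0.95),
                     auc_sd = rep(0.02, 5))
  expect_equal(select_optimal_fraction(ramp), 1.0)
  expect_error(select_optimal_fraction(sw[1, ]), "two valid")
})

test_that("scan-time projection is linear in the spared fraction", {
  expect_equal(scan_time_reduction(0.7), 30)
  expect_equal(scan_time_reduction(0.8), 20)
  expect_equal(scan_time_reduction(1.0), 0)
  expect_error(scan_time_reduction(0), "\\(0, 1\\]")
  expect_error(scan_time_reduction(1.2), "\\(0, 1\\]")
})

test_that("raw-vs-bootstrap agreement uses the k-sigma band", {
  expect_true(agreement_check(0.749, 0.7216, 0.0425))
  expect_false(agreement_check(0.708, 0.6613, 0.0184))
  expect_true(agreement_check(0.66, 0.66, 0)) # raw = mean, any k
  expect_false(agreement_check(0.7, 0.66, 0, k = 0))
  expect_error(agreement_check(0.7, 0.66, -1), "sd")
})
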