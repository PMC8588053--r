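# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Bernoulli log-likelihood of a two-parameter logistic model.
oracle_logistic_loglik <- function(b0, b1, x, y) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta)))
}

# Brute-force logistic MLE by iteratively refined grid search.
oracle_grid_logistic <- function(x, y, b0_lim = c(-20, 20),
                                 b1_lim = c(-10, 10), rounds = 8,
                                 grid_n = 41) {
  b0c <- mean(b0_lim); b1c <- mean(b1_lim)
  w0 <- diff(b0_lim) / 2; w1 <- diff(b1_lim) / 2
  for (r in seq_len(rounds)) {
    b0s <- seq(b0c - w0, b0c + w0, length.out = grid_n)
    b1s <- seq(b1c - w1, b1c + w1, length.out = grid_n)
    ll <- outer(b0s, b1s, Vectorize(function(a, b) {
      oracle_logistic_loglik(a, b, x, y)
    }))
    best <- arrayInd(which.max(ll), dim(ll))
    b0c <- b0s[best[1]]; b1c <- b1s[best[2]]
    w0 <- w0 / 8; w1 <- w1 / 8
  }
  list(beta0 = b0c, beta1 = b1c,
       loglik = oracle_logistic_loglik(b0c, b1c, x, y))
}

# Midrank Mann-Whitney estimate of P(score_pos > score_neg).
oracle_mw_auc <- function(scores, labels) {
  pos <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Exhaustive two-group permutation distribution of the Kruskal-Wallis H
# for given data; returns function mapping an observed H to the exact
# permutation p-value P(H >= h).
oracle_kw_perm <- function(g1, g2) {
  x <- c(g1, g2)
  n <- length(x); n1 <- length(g1)
  cmb <- utils::combn(n, n1)
  H <- apply(cmb, 2, function(ix) {
    g <- factor(replace(rep(2L, n), ix, 1L))
    unname(stats::kruskal.test(x, g)$statistic)
  })
  list(H = H,
       p = function(h) mean(H >= h - 1e-9))
}

# Direct evaluation of uncorrected central-moment skewness/kurtosis,
# expanded without reusing package internals.
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(skewness = m3 / m2^(3 / 2), kurtosis = m4 / m2^2)
}

# Exhaustive Youden search over every observed score as candidate cutoff
# (plus sentinels), by direct confusion-matrix counting.
oracle_youden <- function(scores, labels, halved = TRUE) {
  pos <- as.logical(labels)
  cands <- c(-Inf, sort(unique(scores)), Inf)
  best <- -Inf
  for (ct in cands) {
    se <- mean(scores[pos] >= ct)
    sp <- mean(scores[!pos] < ct)
    yi <- (se + sp - 1) / (if (halved) 2 else 1)
    if (yi > best) best <- yi
  }
  best
}

# Shared synthetic pair for pipeline tests: clearly separated Gammas.
separated_pair <- function(n_datasets = 10, seed = 1) {
  pair_config(gamma_params(shape = 16, scale = 0.5),   # mean 8,  sd 2
              gamma_params(shape = 16, scale = 1.25),  # mean 20, sd 5
              n_a = 60, n_datasets = n_datasets, seed = seed)
}
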