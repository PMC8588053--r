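#' Sample moments for normality screening
#'
#' Mean, skewness and kurtosis using the uncorrected (population-style)
#' central-moment estimators: `skewness = m3 / m2^1.5` and
#' `kurtosis = m4 / m2^2` with `m_k = mean((x - mean(x))^k)`. Kurtosis is
#' reported plain (a Gaussian gives 3, not 0); the Jarque–Bera statistic
#' subtracts the 3 itself.
#'
#' @param values Numeric vector, `length >= 2`, finite, non-constant.
#' @return Object of class `"moment_summary"`: list with `n`, `mean`,
#'   `skewness`, `kurtosis`.
#' @examples
#' sample_moments(c(-1, 0, 1))$skewness # 0
#' @export
sample_moments <- function(values) {
  values <- pore_values(values, "values")
  n <- length(values)
  if (n < 2L) stop_domain("need at least two values")
  if (any(!is.finite(values))) stop_domain("values must be finite")
  m <- mean(values)
  d <- values - m
  m2 <- mean(d^2)
  if (m2 == 0) stop_domain("zero variance: moments are degenerate")
  structure(
    list(n = n, mean = m,
         skewness = mean(d^3) / m2^1.5,
         kurtosis = mean(d^4) / m2^2),
    class = "moment_summary"
  )
}

#' @export
print.moment_summary <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.4g, skewness = %.4g, kurtosis = %.4g\n",
              x$n, x$mean, x$skewness, x$kurtosis))
  invisible(x)
}

moment_summary_from <- function(x) {
  if (inherits(x, "moment_summary")) return(x)
  sample_moments(x)
}

#' Jarque–Bera normality test
#'
#' Combines sample skewness `b1` and (plain) kurtosis `b2` into
#' \deqn{JB = n\left(\frac{b_1^2}{6} + \frac{(b_2-3)^2}{24}\right),}
#' which is zero for exactly Gaussian moments and asymptotically
#' chi-squared with 2 degrees of freedom under normality. The default
#' critical value is the asymptotic 95% quantile (5.99); for the sample
#' sizes typical of AFM scans the finite-sample quantile from
#' [jb_critical()] is noticeably smaller and should be preferred.
#'
#' @param moments A `"moment_summary"` (from [sample_moments()]) or a raw
#'   numeric vector.
#' @param critical_value Rejection threshold for the statistic.
#' @return Object of class `"jb_result"`: list with `statistic`,
#'   `critical_value`, `passes_normality` (`TRUE` iff
#'   `statistic <= critical_value`).
#' @seealso [jb_critical()]
#' @examples
#' m <- structure(list(n = 304, mean = 11.1, skewness = 2.307,
#'                     kurtosis = 9.048), class = "moment_summary")
#' round(jarque_bera(m)$statistic) # 733
#' @export
jarque_bera <- function(moments, critical_value = qchisq(0.95, df = 2)) {
  m <- moment_summary_from(moments)
  if (!is.finite(critical_value) || critical_value < 0) {
    stop_domain("'critical_value' must be a non-negative number")
  }
  stat <- m$n * (m$skewness^2 / 6 + (m$kurtosis - 3)^2 / 24)
  structure(
    list(statistic = stat, critical_value = critical_value,
         passes_normality = stat <= critical_value),
    class = "jb_result"
  )
}

#' @export
print.jb_result <- function(x, ...) {
  cat(sprintf("Jarque-Bera: JB = %.4g (critical %.3g) -> %s\n",
              x$statistic, x$critical_value,
              if (x$passes_normality) "normality not rejected"
              else "normality rejected"))
  invisible(x)
}

# JB statistics for many standard-normal samples of size n, column-wise.
jb_null_statistics <- function(n, replicates) {
  # chunk so the working matrix stays below ~2e7 doubles
  chunk <- max(1L, floor(2e7 / n))
  out <- numeric(0)
  left <- replicates
  while (left > 0L) {
    k <- min(chunk, left)
    M <- matrix(rnorm(n * k), nrow = n, ncol = k)
    mu <- colMeans(M)
    D <- sweep(M, 2L, mu)
    m2 <- colMeans(D^2)
    m3 <- colMeans(D^3)
    m4 <- colMeans(D^4)
    b1 <- m3 / m2^1.5
    b2 <- m4 / m2^2
    out <- c(out, n * (b1^2 / 6 + (b2 - 3)^2 / 24))
    left <- left - k
  }
  out
}

#' Finite-sample Jarque–Bera critical value by Monte Carlo
#'
#' The chi-squared approximation to the JB null distribution is poor at
#' the sample sizes of a single AFM scan series; this function estimates
#' the `(1 - alpha)` null quantile directly by simulating standard-normal
#' samples of size `n`. At `alpha = 0.05` it gives roughly 5.1 for n = 60
#' and roughly 5.7 for n = 304, against the asymptotic 5.99.
#'
#' @param n Sample size (`>= 8`).
#' @param alpha Significance level in (0, 1).
#' @param replicates Number of Monte-Carlo samples (`>= 1e4`).
#' @param seed Optional seed for reproducibility; the caller's RNG state
#'   is restored afterwards.
#' @return The Monte-Carlo `(1 - alpha)` quantile of JB under normality.
#' @export
jb_critical <- function(n, alpha = 0.05, replicates = 1e5, seed = NULL) {
  if (!is.numeric(n) || n < 8) stop_domain("'n' must be at least 8")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop_domain("'alpha' must be in (0, 1)")
  }
  if (!is.numeric(replicates) || replicates < 1e4) {
    stop_domain("'replicates' must be at least 1e4 for a stable quantile")
  }
  stats <- with_seed(seed, jb_null_statistics(as.integer(n),
                                              as.integer(replicates)))
  unname(quantile(stats, probs = 1 - alpha, type = 7))
}

#' Kruskal–Wallis rank test across groups
#'
#' Thin wrapper around [stats::kruskal.test()] (midrank-based H statistic
#' with tie correction, chi-squared p-value on k - 1 degrees of freedom)
#' returning the fields the pipeline reports. When every value in every
#' group is identical the H statistic is defined as 0 with p = 1.
#'
#' @param groups List of at least two non-empty numeric vectors.
#' @return Object of class `"kw_result"`: list with `h_statistic`, `dof`,
#'   `p_value`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_domain("'groups' must be a list of at least two groups")
  }
  if (any(vapply(groups, length, 1L) == 0L)) {
    stop_domain("all groups must be non-empty")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(x)) == 1L) {
    res <- list(h_statistic = 0, dof = length(groups) - 1L, p_value = 1)
  } else {
    kt <- kruskal.test(x, g)
    res <- list(h_statistic = unname(kt$statistic),
                dof = unname(kt$parameter),
                p_value = kt$p.value)
  }
  structure(res, class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
              x$h_statistic, x$dof, x$p_value))
  invisible(x)
}

#' Gamma shape/scale parameter pair
#'
#' Container for the two-parameter Gamma model of a right-skewed pore-size
#' distribution, density
#' `f(x) = x^(a-1) exp(-x/b) / (b^a Gamma(a))` for `x >= 0` with shape
#' `a > 0` and scale `b > 0` (nm). Implied mean is `a*b` and implied
#' skewness `2/sqrt(a)`.
#'
#' @param shape Shape parameter `a > 0`.
#' @param scale Scale parameter `b > 0` (nm).
#' @return Object of class `"gamma_params"`.
#' @export
gamma_params <- function(shape, scale) {
  if (!is.finite(shape) || shape <= 0) stop_domain("'shape' must be > 0")
  if (!is.finite(scale) || scale <= 0) stop_domain("'scale' must be > 0")
  structure(list(shape = shape, scale = scale), class = "gamma_params")
}

#' @export
print.gamma_params <- function(x, ...) {
  cat(sprintf(
    "Gamma(shape = %.4g, scale = %.4g nm): mean %.4g nm, skewness %.4g\n",
    x$shape, x$scale, x$shape * x$scale, 2 / sqrt(x$shape)))
  invisible(x)
}

gamma_loglik <- function(x, shape, scale) {
  sum(dgamma(x, shape = shape, scale = scale, log = TRUE))
}

#' Maximum-likelihood Gamma fit
#'
#' Fits shape and scale by Newton iteration on the profile log-likelihood
#' of the shape: with `s = log(mean(x)) - mean(log(x))`, the MLE shape
#' solves `log(a) - digamma(a) = s` and the scale is `mean(x)/a`. The
#' iteration starts from the method-of-moments estimate and stops at a
#' relative tolerance of 1e-10 (at most 200 iterations).
#'
#' @param values Positive numeric vector, `length >= 10`.
#' @return A [gamma_params()] object with attribute `"loglik"` (the
#'   maximized log-likelihood) and `"iterations"`.
#' @seealso [gamma_fit_moments()]
#' @export
gamma_fit_mle <- function(values) {
  x <- pore_values(values, "values")
  if (length(x) < 10L) stop_domain("need at least 10 values for a Gamma fit")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_domain("Gamma fitting requires strictly positive finite values")
  }
  mx <- mean(x)
  m2 <- mean((x - mx)^2)
  if (m2 == 0) stop_domain("zero variance: Gamma fit is degenerate")
  s <- log(mx) - mean(log(x))
  a <- mx^2 / m2 # method-of-moments start
  iter <- 0L
  for (iter in seq_len(200L)) {
    g <- log(a) - digamma(a) - s
    gp <- 1 / a - trigamma(a)
    a_new <- a - g / gp
    if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
    done <- abs(a_new - a) <= 1e-10 * a
    a <- a_new
    if (done) break
  }
  fit <- gamma_params(shape = a, scale = mx / a)
  attr(fit, "loglik") <- gamma_loglik(x, a, mx / a)
  attr(fit, "iterations") <- iter
  fit
}

#' Gamma parameters from mean and skewness
#'
#' Inverts the Gamma moment identities `mean = a*b`,
#' `skewness = 2/sqrt(a)`: `shape = (2/skewness)^2`,
#' `scale = mean/shape`. This is how the synthetic presets turn a reported
#' (mean, skewness) pair into a simulable distribution.
#'
#' @param mean Target mean (nm), `> 0`.
#' @param skewness Target skewness, `> 0`.
#' @return A [gamma_params()] object.
#' @examples
#' gamma_fit_moments(9.45, 2.314) # shape ~0.747, scale ~12.65
#' @export
gamma_fit_moments <- function(mean, skewness) {
  if (!is.finite(mean) || mean <= 0) stop_domain("'mean' must be > 0")
  if (!is.finite(skewness) || skewness <= 0) {
    stop_domain("'skewness' must be > 0 (Gamma is right-skewed)")
  }
  shape <- (2 / skewness)^2
  gamma_params(shape = shape, scale = mean / shape)
}

#' Normality-gated two-sample discrimination test
#'
#' Decides whether two membranes can be distinguished by their pore-radius
#' distributions. Each sample is first screened with [jarque_bera()]; if
#' both pass, the comparison is parametric: a Brown–Forsythe/Levene check
#' of variance homogeneity (absolute deviations from the group median, via
#' [car::leveneTest()]) selects a pooled or Welch two-sample t-test.
#' If either sample fails normality, the comparison falls back to the
#' rank-based [kruskal_wallis()] test on the two groups.
#'
#' @param set_a,set_b `pore_set` objects or numeric vectors.
#' @param alpha Significance level for every sub-test (default 0.05).
#' @param jb_critical_value Critical value(s) for the normality screen;
#'   a single number or one per sample. Defaults to the asymptotic
#'   chi-squared quantile at `1 - alpha`; pass values from
#'   [jb_critical()] for finite-sample gating.
#' @return Object of class `"discrimination_result"`: list with `branch`
#'   (`"parametric"` or `"nonparametric"`), `statistic`, `p_value`,
#'   `reject` (at `alpha`), the two `"jb_result"`s, and `levene_p`
#'   (`NA` on the non-parametric branch).
#' @export
pairwise_discrimination <- function(set_a, set_b, alpha = 0.05,
                                    jb_critical_value = NULL) {
  a <- pore_values(set_a, "set_a")
  b <- pore_values(set_b, "set_b")
  if (length(a) < 2L || length(b) < 2L) {
    stop_domain("both samples need at least two values")
  }
  if (is.null(jb_critical_value)) {
    jb_critical_value <- qchisq(1 - alpha, df = 2)
  }
  jb_critical_value <- rep_len(jb_critical_value, 2L)
  jb_a <- jarque_bera(a, jb_critical_value[1L])
  jb_b <- jarque_bera(b, jb_critical_value[2L])

  if (jb_a$passes_normality && jb_b$passes_normality) {
    grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
    lev <- car::leveneTest(c(a, b), grp, center = median)
    levene_p <- lev[["Pr(>F)"]][1L]
    tt <- t.test(a, b, var.equal = levene_p > alpha)
    res <- list(branch = "parametric",
                statistic = unname(tt$statistic),
                p_value = tt$p.value,
                levene_p = levene_p)
  } else {
    kw <- kruskal_wallis(list(a, b))
    res <- list(branch = "nonparametric",
                statistic = kw$h_statistic,
                p_value = kw$p_value,
                levene_p = NA_real_)
  }
  res$reject <- res$p_value < alpha
  res$alpha <- alpha
  res$jb_a <- jb_a
  res$jb_b <- jb_b
  structure(res, class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("Two-sample discrimination (%s branch):\n", x$branch))
  cat(sprintf("  statistic = %.4g, p = %.4g -> %s at alpha = %g\n",
              x$statistic, x$p_value,
              if (x$reject) "distinguishable" else "not distinguishable",
              x$alpha))
  invisible(x)
}
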