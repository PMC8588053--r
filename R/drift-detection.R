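#' Adjusted coefficient of determination
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)` for `p` fitted parameters
#' (excluding the residual variance). Penalizes the raw R-squared for
#' model size; used as the periodicity indicator in drift screening.
#'
#' @param r2 Raw coefficient of determination.
#' @param n Number of observations (`> p + 1`).
#' @param p Number of fitted parameters.
#' @return Adjusted R-squared.
#' @examples
#' adjusted_r2(0.5, 60, 4) # 0.4636
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (!is.finite(r2)) stop_domain("'r2' must be finite")
  if (n <= p + 1) stop_domain("need n > p + 1 for the adjustment")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# OLS (optionally weighted) fit of a Fourier series with fundamental
# frequency f (cycles per acquisition index). Returns coefficients and SSE.
fourier_ls <- function(y, t, f, harmonics, w = NULL) {
  X <- matrix(1, nrow = length(y), ncol = 1L + 2L * harmonics)
  for (k in seq_len(harmonics)) {
    X[, 2L * k] <- cos(2 * pi * k * f * t)
    X[, 2L * k + 1L] <- sin(2 * pi * k * f * t)
  }
  if (is.null(w)) {
    fit <- stats::lm.fit(X, y)
  } else {
    fit <- stats::lm.wfit(X, y, w = w)
  }
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  fitted <- drop(X %*% coef)
  list(coef = coef, fitted = fitted, resid = y - fitted,
       sse = sum((y - fitted)^2))
}

bisquare_weights <- function(r, tuning = 4.685) {
  s <- median(abs(r)) / 0.6745
  if (s <= .Machine$double.eps) return(rep(1, length(r)))
  u <- r / (tuning * s)
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  w
}

#' Detect periodic instrument drift by a fitted Fourier series
#'
#' Fits `a0 + sum_k [a_k cos(k w t) + b_k sin(k w t)]` to the measurements
#' in acquisition order, minimizing squared residuals over both the
#' coefficients and the fundamental frequency. For a fixed frequency the
#' model is linear, so the search is a multistart over candidate
#' fundamentals (log-spaced in (1/n, 1/2) cycles per index) with local
#' refinement of the best brackets by [stats::optimize()]. A high adjusted
#' R-squared indicates periodic structure — the signature of stage drift —
#' whereas values well below 1 on independent noise rule it out.
#'
#' With `robust = TRUE` the coefficients are re-estimated by iteratively
#' reweighted least squares with Tukey bisquare weights (tuning constant
#' 4.685, 10 iterations) at the selected frequency, down-weighting
#' outlying pores; the R-squared of a robust fit is computed from the
#' bisquare-weighted sums of squares, so rejected outliers do not mask an
#' otherwise periodic series.
#'
#' @param series Numeric vector of pore radii (nm) in acquisition order,
#'   or a `pore_set` (values taken in acquisition order).
#' @param harmonics Number of harmonics (default 2). The fitted parameter
#'   count is `2 * harmonics + 2` (constant, cosine/sine amplitudes, and
#'   the fundamental frequency).
#' @param robust Apply bisquare reweighting (default `FALSE`).
#' @param threshold Drift flag threshold on the adjusted R-squared
#'   (default 0.8).
#' @param n_starts Number of multistart frequencies (default 20).
#' @param tol Convergence tolerance for the frequency refinement.
#' @return Object of class `"drift_fit"`: list with `frequency`,
#'   `coefficients`, `fitted`, `residuals`, `r2`, `r2_adjusted`, `robust`,
#'   `drift_flag`, `threshold`, `n`, `p`.
#' @export
fit_fourier <- function(series, harmonics = 2, robust = FALSE,
                        threshold = 0.8, n_starts = 20, tol = 1e-9) {
  if (inherits(series, "pore_set")) {
    series <- series$values[order(series$acquisition_index)]
  }
  y <- as.numeric(series)
  n <- length(y)
  p <- 2L * harmonics + 2L
  if (harmonics < 1) stop_domain("'harmonics' must be at least 1")
  if (n <= p + 1L) {
    stop_domain("need more than ", p + 1L, " points for ", harmonics,
                " harmonic(s)")
  }
  t <- seq_len(n)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop_domain("constant series: drift fit is degenerate")

  f_grid <- exp(seq(log(1 / n), log(0.5), length.out = n_starts))
  sse_grid <- vapply(f_grid, function(f) fourier_ls(y, t, f, harmonics)$sse,
                     numeric(1))
  # refine the most promising brackets; the SSE landscape is multimodal
  ord <- order(sse_grid)
  best_f <- f_grid[ord[1L]]
  best_sse <- sse_grid[ord[1L]]
  for (i in ord[seq_len(min(5L, n_starts))]) {
    lo <- if (i == 1L) 1 / (2 * n) else f_grid[i - 1L]
    hi <- if (i == n_starts) 0.5 else f_grid[i + 1L]
    opt <- optimize(function(f) fourier_ls(y, t, f, harmonics)$sse,
                    interval = c(lo, hi), tol = tol)
    if (opt$objective < best_sse) {
      best_sse <- opt$objective
      best_f <- opt$minimum
    }
  }

  fit <- fourier_ls(y, t, best_f, harmonics)
  if (robust) {
    w <- rep(1, n)
    for (it in seq_len(10L)) {
      w <- bisquare_weights(fit$resid)
      if (all(w == 0)) {
        w <- rep(1, n)
        break
      }
      fit <- fourier_ls(y, t, best_f, harmonics, w = w)
    }
    # score the robust fit on the weighted sums of squares, so that
    # down-weighted outliers do not dominate the variance explained
    ybar_w <- sum(w * y) / sum(w)
    sst_w <- sum(w * (y - ybar_w)^2)
    r2 <- if (sst_w > 0) 1 - sum(w * fit$resid^2) / sst_w else 0
  } else {
    r2 <- 1 - fit$sse / sst
  }
  r2a <- adjusted_r2(r2, n, p)
  coefs <- fit$coef
  names(coefs) <- c("a0", as.vector(rbind(paste0("a", seq_len(harmonics)),
                                          paste0("b", seq_len(harmonics)))))
  structure(
    list(frequency = best_f, coefficients = coefs, fitted = fit$fitted,
         residuals = fit$resid, r2 = r2, r2_adjusted = r2a,
         robust = robust, drift_flag = r2a >= threshold,
         threshold = threshold, n = n, p = p),
    class = "drift_fit"
  )
}

#' @export
print.drift_fit <- function(x, ...) {
  cat(sprintf(
    "Fourier drift fit (%s): f = %.4g cycles/index, R2 = %.3f, adj. R2 = %.3f\n",
    if (x$robust) "robust" else "least squares", x$frequency, x$r2,
    x$r2_adjusted))
  cat(sprintf("  drift %s (threshold %.2f on adjusted R2)\n",
              if (x$drift_flag) "FLAGGED" else "not detected", x$threshold))
  invisible(x)
}

#' Environmental-shift screen across scan locations
#'
#' Applies the Kruskal–Wallis rank test to pore radii grouped by scan
#' location. A non-significant p-value is the expected outcome for a
#' stable sample: it means no detectable location-to-location shift such
#' as progressive drying (tapping mode) or continued swelling (fluid
#' mode).
#'
#' @param dataset A `pore_set` with at least two distinct location IDs.
#' @return A `"kw_result"` (see [kruskal_wallis()]).
#' @export
location_shift_test <- function(dataset) {
  if (!inherits(dataset, "pore_set")) {
    stop_domain("'dataset' must be a pore_set")
  }
  groups <- split(dataset$values, dataset$location_ids)
  if (length(groups) < 2L) {
    stop_domain("need at least two distinct scan locations")
  }
  kruskal_wallis(groups)
}
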