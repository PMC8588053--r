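# Coerce labels to logical positives. Accepts logical, 0/1 numeric, or a
# two-level factor/character (larger level = positive, by sort order).
as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) {
      stop_domain("numeric labels must be coded 0/1")
    }
    return(labels == 1)
  }
  u <- sort(unique(as.character(labels)))
  if (length(u) > 2L) stop_domain("labels must have exactly two classes")
  as.character(labels) == u[length(u)]
}

#' Binary logistic regression on pore radius
#'
#' Fits the binomial-link model
#' `logit(p_i) = beta0 + beta1 * x_i`
#' by Newton–Raphson on the Bernoulli log-likelihood (with step-halving),
#' iterating until the Euclidean norm of the score vector falls below
#' `tol`. The positive class is by convention the larger-MWCO membrane,
#' so `beta1 > 0` whenever the positive class has stochastically larger
#' radii.
#'
#' Completely (or quasi-completely) separated data have no finite MLE;
#' in that case the coefficients are capped at `|beta| <= cap`, the fit
#' is flagged `separated = TRUE` and a warning is raised. The capped fit
#' still orders observations correctly, so downstream ROC analysis is
#' unaffected.
#'
#' @param x Numeric covariate (pore radius, nm).
#' @param labels Binary class labels (logical, 0/1, or two-level factor;
#'   the lexically larger level is the positive class).
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the gradient norm.
#' @param cap Coefficient cap applied on separation.
#' @return Object of class `"logistic_model"`: list with `beta0`, `beta1`,
#'   `iterations`, `gradient_norm`, `converged`, `separated`, `loglik`,
#'   `se` (standard errors from the observed information; `NA` when
#'   separated).
#' @examples
#' set.seed(1)
#' x <- c(rgamma(50, 2, 0.5), rgamma(50, 6, 0.5))
#' y <- rep(c(0, 1), each = 50)
#' fit_logistic(x, y)
#' @export
fit_logistic <- function(x, labels, max_iter = 100, tol = 1e-8, cap = 50) {
  x <- as.numeric(x)
  y <- as_positive(labels)
  if (length(x) != length(y)) stop_domain("'x' and 'labels' lengths differ")
  if (any(!is.finite(x))) stop_domain("'x' must be finite")
  if (!any(y) || all(y)) stop_domain("both classes must be present")

  X <- cbind(1, x)
  yn <- as.numeric(y)
  # with a single covariate the MLE is infinite exactly when the classes
  # do not overlap (complete/quasi-complete separation)
  separated <- min(x[y]) >= max(x[!y]) || max(x[y]) <= min(x[!y])
  beta <- c(0, 0)
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(yn * eta - log1p(exp(eta)))
  }
  ll <- loglik(beta)
  grad_norm <- Inf
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    grad <- drop(crossprod(X, yn - p))
    grad_norm <- sqrt(sum(grad^2))
    if (grad_norm < tol) break
    w <- p * (1 - p)
    H <- crossprod(X, X * w)
    delta <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(delta)) { separated <- TRUE; break }
    # step-halving: never accept a decrease in log-likelihood
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_cand <- loglik(cand)
      if (is.finite(ll_cand) && ll_cand >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { cand <- beta; ll_cand <- ll; break }
    }
    beta <- cand
    ll <- ll_cand
    if (any(abs(beta) > cap)) {
      separated <- TRUE
      break
    }
    if (separated && grad_norm < 1e-4) break # flat separated plateau
  }
  if (separated) {
    beta <- pmin(pmax(beta, -cap), cap)
    ll <- loglik(beta)
    warning("separation detected: coefficients capped at |beta| <= ", cap,
            call. = FALSE)
  }
  se <- c(NA_real_, NA_real_)
  if (!separated) {
    p <- plogis(drop(X %*% beta))
    H <- crossprod(X, X * (p * (1 - p)))
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) se <- unname(sqrt(diag(V)))
  }
  structure(
    list(beta0 = unname(beta[1L]), beta1 = unname(beta[2L]),
         iterations = iter,
         gradient_norm = grad_norm, converged = grad_norm < tol,
         separated = separated, loglik = ll, se = se),
    class = "logistic_model"
  )
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("Logistic model: logit(p) = %.4g + %.4g * x\n",
              x$beta0, x$beta1))
  cat(sprintf("  %d iterations, gradient norm %.3g%s\n", x$iterations,
              x$gradient_norm,
              if (x$separated) " [SEPARATED: coefficients capped]" else ""))
  invisible(x)
}

#' @param object A `"logistic_model"`.
#' @param newdata Numeric covariate values to score.
#' @param type `"response"` for probabilities, `"link"` for the linear
#'   predictor.
#' @param ... Unused.
#' @rdname fit_logistic
#' @export
predict.logistic_model <- function(object, newdata,
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- object$beta0 + object$beta1 * as.numeric(newdata)
  if (type == "link") eta else plogis(eta)
}

#' Empirical ROC curve
#'
#' Builds the receiver operating characteristic of a score against binary
#' labels. Cutoffs are placed at the midpoints between consecutive
#' distinct score values, plus `-Inf` and `+Inf` sentinels, and an
#' observation is called positive when `score >= cutoff`. Sensitivity is
#' `TP/(TP+FN)` and specificity `TN/(TN+FP)` at each cutoff, so the curve
#' runs from (0,0) (cutoff `+Inf`) to (1,1) (cutoff `-Inf`) in
#' (1 - specificity, sensitivity) space. The trapezoidal AUC equals the
#' midrank Mann–Whitney estimate of `P(score_pos > score_neg)`.
#'
#' @param scores Numeric scores (larger = more "positive"); typically raw
#'   radii or logistic probabilities — any monotone transform gives the
#'   identical curve.
#' @param labels Binary labels (see [fit_logistic()] for coding).
#' @param halved Use the halved Youden convention `(Se+Sp-1)/2` (default);
#'   `FALSE` gives the standard `Se+Sp-1`.
#' @return Object of class `"roc_curve"`: list with `points` (data frame
#'   `cutoff`, `sensitivity`, `specificity`), `auc`, `youden`,
#'   `optimal_cutoff`, `halved`.
#' @export
roc_curve <- function(scores, labels, halved = TRUE) {
  s <- as.numeric(scores)
  y <- as_positive(labels)
  if (length(s) != length(y)) stop_domain("lengths differ")
  if (any(!is.finite(s))) stop_domain("scores must be finite")
  if (!any(y) || all(y)) stop_domain("both classes must be present")

  us <- sort(unique(s))
  cutoffs <- c(-Inf, if (length(us) > 1L) (us[-length(us)] + us[-1L]) / 2,
               Inf)
  pos <- s[y]
  neg <- s[!y]
  se <- vapply(cutoffs, function(ct) mean(pos >= ct), numeric(1))
  sp <- vapply(cutoffs, function(ct) mean(neg < ct), numeric(1))

  # order points along increasing 1 - specificity (decreasing cutoff)
  ord <- order(cutoffs, decreasing = TRUE)
  fpr <- 1 - sp[ord]
  tpr <- se[ord]
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)

  yi_all <- (se + sp - 1) / (if (halved) 2 else 1)
  best <- max(yi_all)
  # ties broken toward the lower cutoff
  opt <- min(cutoffs[yi_all >= best - 1e-12])

  structure(
    list(points = data.frame(cutoff = cutoffs, sensitivity = se,
                             specificity = sp),
         auc = auc, youden = best, optimal_cutoff = opt, halved = halved),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: %d cutoffs, AUC = %.4f (%s)\n",
              nrow(x$points), x$auc, auc_category(x$auc)))
  cat(sprintf("  Youden %s = %.4f at cutoff %.4g\n",
              if (x$halved) "(Se+Sp-1)/2" else "Se+Sp-1",
              x$youden, x$optimal_cutoff))
  invisible(x)
}

#' Area under the ROC curve
#'
#' @param roc A `"roc_curve"` object.
#' @return The trapezoidal AUC in `[0, 1]`.
#' @export
auc <- function(roc) {
  if (!inherits(roc, "roc_curve")) stop_domain("'roc' must be a roc_curve")
  roc$auc
}

#' Youden index and optimal cutoff
#'
#' Maximum of `(Se + Sp - 1)/2` over cutoffs (the halved convention used
#' throughout this pipeline, bounded by 0.5 for a perfect classifier), or
#' the standard `Se + Sp - 1` with `halved = FALSE`. Ties are broken
#' toward the lower cutoff.
#'
#' @param roc A `"roc_curve"` object.
#' @param halved Halve the index (default `TRUE`).
#' @return List with `youden` and `cutoff`.
#' @export
youden <- function(roc, halved = TRUE) {
  if (!inherits(roc, "roc_curve")) stop_domain("'roc' must be a roc_curve")
  yi <- (roc$points$sensitivity + roc$points$specificity - 1) /
    (if (halved) 2 else 1)
  best <- max(yi)
  list(youden = best,
       cutoff = min(roc$points$cutoff[yi >= best - 1e-12]))
}

#' Confusion counts and accuracy at a cutoff
#'
#' Calls an observation positive when `score >= cutoff` and tabulates the
#' confusion matrix; accuracy is `(TP + TN) / N`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param cutoff Decision threshold.
#' @return Object of class `"classification_metrics"`: list with `tp`,
#'   `tn`, `fp`, `fn`, `n_total`, `accuracy`.
#' @export
accuracy_at_cutoff <- function(scores, labels, cutoff) {
  s <- as.numeric(scores)
  y <- as_positive(labels)
  if (length(s) != length(y)) stop_domain("lengths differ")
  if (length(s) == 0L) stop_domain("no observations to classify")
  call_pos <- s >= cutoff
  tp <- sum(call_pos & y)
  tn <- sum(!call_pos & !y)
  fp <- sum(call_pos & !y)
  fn <- sum(!call_pos & y)
  structure(
    list(tp = tp, tn = tn, fp = fp, fn = fn, n_total = length(s),
         accuracy = (tp + tn) / length(s)),
    class = "classification_metrics"
  )
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d  (N = %d): accuracy %.3f\n",
              x$tp, x$tn, x$fp, x$fn, x$n_total, x$accuracy))
  invisible(x)
}

#' Categorical discrimination strength of an AUC
#'
#' `"high"` for AUC in `[0.8, 1]`, `"medium"` for `[0.7, 0.8)`, `"low"`
#' below 0.7 (boundaries resolved upward).
#'
#' @param auc AUC value(s) in `[0, 1]`.
#' @return Character vector of labels.
#' @examples
#' auc_category(c(0.852, 0.762, 0.579)) # high medium low
#' @export
auc_category <- function(auc) {
  if (any(!is.finite(auc)) || any(auc < 0) || any(auc > 1)) {
    stop_domain("AUC must lie in [0, 1]")
  }
  ifelse(auc >= 0.8, "high", ifelse(auc >= 0.7, "medium", "low"))
}

#' Stratified hold-out split
#'
#' Partitions observations into evaluation and training subsets, class by
#' class, so both partitions keep the class balance. The per-class
#' evaluation count is `round(eval_fraction * n_class)` using R's
#' round-half-to-even rule; the remainder trains the model. Note the
#' pipeline's convention: the *evaluation* partition is the large one
#' (default 80%) and the model is trained on the 20% remainder.
#'
#' @param labels Binary class labels, one per observation.
#' @param eval_fraction Fraction of each class assigned to the evaluation
#'   partition, in (0, 1); default 0.8.
#' @param seed Optional seed (caller's RNG state is restored).
#' @return List with integer index vectors `train` and `eval`; disjoint
#'   and jointly exhaustive.
#' @export
holdout_split <- function(labels, eval_fraction = 0.8, seed = NULL) {
  y <- as_positive(labels)
  if (!is.finite(eval_fraction) || eval_fraction <= 0 || eval_fraction >= 1) {
    stop_domain("'eval_fraction' must be in (0, 1)")
  }
  idx_by_class <- split(seq_along(y), y)
  if (length(idx_by_class) < 2L || any(lengths(idx_by_class) < 2L)) {
    stop_domain("each class needs at least two members to split")
  }
  picks <- with_seed(seed, lapply(idx_by_class, function(idx) {
    n_eval <- round(eval_fraction * length(idx))
    if (n_eval < 1L || n_eval >= length(idx)) {
      stop_domain("split leaves an empty partition for one class ",
                  "(class n = ", length(idx), ", eval_fraction = ",
                  eval_fraction, ")")
    }
    sample(idx, n_eval)
  }))
  eval_idx <- sort(unlist(picks, use.names = FALSE))
  list(train = setdiff(seq_along(y), eval_idx), eval = eval_idx)
}
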