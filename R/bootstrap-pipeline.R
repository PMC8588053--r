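#' Configuration of a two-class parametric-bootstrap classification run
#'
#' Describes one membrane pair: the Gamma models of the two classes, the
#' per-class sample sizes, the number of Monte-Carlo replicate datasets
#' and the hold-out evaluation fraction. Class B is the positive class by
#' convention — pass the larger-MWCO membrane as `gamma_b` so the fitted
#' logistic slope is positive.
#'
#' @param gamma_a,gamma_b [gamma_params()] for the negative (smaller
#'   MWCO) and positive (larger MWCO) classes.
#' @param n_a,n_b Per-class sample sizes (`>= 10`), e.g. 60 for tapping
#'   and 304 for fluid mode.
#' @param n_datasets Number of Monte-Carlo replicate datasets
#'   (default 10).
#' @param eval_fraction Fraction of each class used for ROC evaluation;
#'   the remainder trains the logistic model (default 0.8, i.e. train on
#'   20%).
#' @param seed Master seed; every replicate draws its own substream.
#' @return Object of class `"pair_config"`.
#' @export
pair_config <- function(gamma_a, gamma_b, n_a, n_b = n_a, n_datasets = 10,
                        eval_fraction = 0.8, seed = 1) {
  if (!inherits(gamma_a, "gamma_params") ||
      !inherits(gamma_b, "gamma_params")) {
    stop_domain("'gamma_a'/'gamma_b' must be gamma_params objects")
  }
  if (n_a < 10 || n_b < 10) stop_domain("class sizes must be at least 10")
  if (n_datasets < 2) stop_domain("'n_datasets' must be at least 2")
  if (eval_fraction <= 0 || eval_fraction >= 1) {
    stop_domain("'eval_fraction' must be in (0, 1)")
  }
  structure(
    list(gamma_a = gamma_a, gamma_b = gamma_b, n_a = as.integer(n_a),
         n_b = as.integer(n_b), n_datasets = as.integer(n_datasets),
         eval_fraction = eval_fraction, seed = seed),
    class = "pair_config"
  )
}

#' Monte-Carlo generation of two-class replicate datasets
#'
#' Draws `n_datasets` independent labeled datasets, each with `n_a`
#' radii from the class-A Gamma and `n_b` from the class-B Gamma.
#' Replicate `r` uses the r-th substream of the master seed, so a dataset
#' is reproducible from `(seed, r)` alone.
#'
#' @param config A [pair_config()].
#' @return List of length `n_datasets`; each element is a list with
#'   numeric `values` and logical `labels` (`TRUE` = class B, the
#'   positive class).
#' @export
generate_mc_datasets <- function(config) {
  if (!inherits(config, "pair_config")) {
    stop_domain("'config' must be a pair_config")
  }
  seeds <- sub_seeds(config$seed, config$n_datasets)
  lapply(seeds, function(s) {
    with_seed(s, {
      a <- rgamma(config$n_a, shape = config$gamma_a$shape,
                  scale = config$gamma_a$scale)
      b <- rgamma(config$n_b, shape = config$gamma_b$shape,
                  scale = config$gamma_b$scale)
      list(values = c(a, b),
           labels = rep(c(FALSE, TRUE), c(config$n_a, config$n_b)))
    })
  })
}

# One hold-out replicate: split, train logistic on the small partition,
# evaluate ROC/AUC/Youden/accuracy on the large one. Separation warnings
# are counted, not propagated.
classify_replicate <- function(values, labels, eval_fraction, split_seed,
                               cutoff_rule = "youden") {
  parts <- holdout_split(labels, eval_fraction, seed = split_seed)
  n_sep <- 0L
  model <- withCallingHandlers(
    fit_logistic(values[parts$train], labels[parts$train]),
    warning = function(w) {
      n_sep <<- n_sep + 1L
      invokeRestart("muffleWarning")
    }
  )
  scores <- predict(model, values[parts$eval])
  roc <- roc_curve(scores, labels[parts$eval])
  cutoff <- if (cutoff_rule == "youden") roc$optimal_cutoff else 0.5
  metrics <- accuracy_at_cutoff(scores, labels[parts$eval], cutoff)
  list(auc = roc$auc, youden = roc$youden, accuracy = metrics$accuracy,
       beta0 = model$beta0, beta1 = model$beta1,
       separated = model$separated, n_sep = n_sep,
       n_train = length(parts$train), n_eval = length(parts$eval))
}

agg_mean_sd <- function(v) c(mean = mean(v), sd = sd(v))

replicate_table <- function(config, rep_seeds, cutoff_rule) {
  rows <- lapply(seq_len(config$n_datasets), function(r) {
    data <- with_seed(rep_seeds[r, 1L], {
      a <- rgamma(config$n_a, shape = config$gamma_a$shape,
                  scale = config$gamma_a$scale)
      b <- rgamma(config$n_b, shape = config$gamma_b$shape,
                  scale = config$gamma_b$scale)
      list(values = c(a, b),
           labels = rep(c(FALSE, TRUE), c(config$n_a, config$n_b)))
    })
    res <- classify_replicate(data$values, data$labels,
                              config$eval_fraction, rep_seeds[r, 2L],
                              cutoff_rule)
    data.frame(replicate = r, auc = res$auc, youden = res$youden,
               accuracy = res$accuracy, beta0 = res$beta0,
               beta1 = res$beta1, separated = res$separated,
               n_train = res$n_train, n_eval = res$n_eval)
  })
  do.call(rbind, rows)
}

#' Replicate hold-out classification of one membrane pair
#'
#' The headline bootstrap analysis for a single pair: for each of the
#' `n_datasets` Monte-Carlo replicates, draw the two-class dataset from
#' the configured Gammas, hold out `eval_fraction` of each class for
#' evaluation, fit the logistic model on the remainder, and score the
#' evaluation partition (ROC, AUC, halved Youden index, accuracy at the
#' Youden-optimal cutoff). Results are aggregated as mean and standard
#' deviation over replicates.
#'
#' @param config A [pair_config()].
#' @param cutoff_rule Cutoff for the accuracy metric: `"youden"` (the
#'   replicate's Youden-optimal cutoff, default) or `"half"` (probability
#'   0.5).
#' @return Object of class `"pair_classification"`: list with `summary`
#'   (one-row data frame of means and SDs for auc, accuracy, youden,
#'   beta0, beta1), `replicates` (per-replicate data frame), `config`,
#'   `n_separated`.
#' @examples
#' cfg <- pair_config(gamma_fit_moments(7.34, 2.599),
#'                    gamma_fit_moments(9.45, 2.314), n_a = 60, seed = 7)
#' run_pair_classification(cfg)
#' @export
run_pair_classification <- function(config,
                                    cutoff_rule = c("youden", "half")) {
  if (!inherits(config, "pair_config")) {
    stop_domain("'config' must be a pair_config")
  }
  cutoff_rule <- match.arg(cutoff_rule)
  rep_seeds <- matrix(sub_seeds(config$seed, 2L * config$n_datasets),
                      ncol = 2L)
  reps <- replicate_table(config, rep_seeds, cutoff_rule)
  summ <- data.frame(
    auc_mean = mean(reps$auc), auc_sd = sd(reps$auc),
    acc_mean = mean(reps$accuracy), acc_sd = sd(reps$accuracy),
    youden_mean = mean(reps$youden), youden_sd = sd(reps$youden),
    beta0_mean = mean(reps$beta0), beta0_sd = sd(reps$beta0),
    beta1_mean = mean(reps$beta1), beta1_sd = sd(reps$beta1)
  )
  structure(
    list(summary = summ, replicates = reps, config = config,
         n_separated = sum(reps$separated)),
    class = "pair_classification"
  )
}

#' @export
print.pair_classification <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Replicate hold-out classification (%d datasets):\n",
              nrow(x$replicates)))
  cat(sprintf("  AUC      %.4f +/- %.4f  (%s)\n", s$auc_mean, s$auc_sd,
              auc_category(s$auc_mean)))
  cat(sprintf("  Accuracy %.3f +/- %.3f\n", s$acc_mean, s$acc_sd))
  cat(sprintf("  Youden   %.3f +/- %.3f\n", s$youden_mean, s$youden_sd))
  cat(sprintf("  beta0    %.4f +/- %.4f\n", s$beta0_mean, s$beta0_sd))
  cat(sprintf("  beta1    %.4f +/- %.4f\n", s$beta1_mean, s$beta1_sd))
  if (x$n_separated > 0) {
    cat(sprintf("  (%d replicate(s) hit separation; coefficients capped)\n",
                x$n_separated))
  }
  invisible(x)
}

#' Test-size sweep over dataset fractions
#'
#' Repeats the replicate hold-out classification while scaling the
#' per-class bootstrapped dataset size by each fraction `f`: the scaled
#' class size is `round(f * n_class)`, which is then split
#' `eval_fraction : (1 - eval_fraction)` as usual (at the defaults,
#' `f = 0.7` with class n = 60 gives a 34:8 evaluation:training split per
#' class). Fractions whose scaled size cannot be split (an empty
#' partition) are reported with `valid = FALSE` and the sweep continues.
#' Each fraction uses its own substream of the master seed, so results
#' for a fraction do not depend on which other fractions are swept.
#'
#' @param config A [pair_config()]; its `n_a`/`n_b` are the full (100%)
#'   class sizes.
#' @param fractions Vector of fractions in (0, 1], default
#'   `seq(0.1, 1, by = 0.1)`.
#' @param cutoff_rule Passed to [run_pair_classification()].
#' @return Object of class `"sweep_result"`: data frame with one row per
#'   fraction — `fraction`, scaled sizes `n_a`, `n_b`, per-class
#'   `n_eval_a`, `n_train_a`, the aggregated `auc_mean`, `auc_sd`,
#'   `acc_mean`, `acc_sd`, `youden_mean`, `youden_sd`, `beta0_mean`,
#'   `beta0_sd`, `beta1_mean`, `beta1_sd`, and `valid`.
#' @seealso [select_optimal_fraction()], [scan_time_reduction()]
#' @export
sweep_test_size <- function(config, fractions = seq(0.1, 1, by = 0.1),
                            cutoff_rule = c("youden", "half")) {
  if (!inherits(config, "pair_config")) {
    stop_domain("'config' must be a pair_config")
  }
  cutoff_rule <- match.arg(cutoff_rule)
  if (length(fractions) == 0 || any(fractions <= 0) || any(fractions > 1)) {
    stop_domain("'fractions' must lie in (0, 1]")
  }
  fr_seeds <- sub_seeds(config$seed, length(fractions))
  rows <- lapply(seq_along(fractions), function(j) {
    f <- fractions[j]
    na <- as.integer(round(f * config$n_a))
    nb <- as.integer(round(f * config$n_b))
    base <- data.frame(fraction = f, n_a = na, n_b = nb)
    res <- tryCatch({
      cfg <- config
      cfg$n_a <- na
      cfg$n_b <- nb
      cfg$seed <- fr_seeds[j]
      if (na < 2L || nb < 2L) stop_domain("scaled class size below 2")
      rep_seeds <- matrix(sub_seeds(cfg$seed, 2L * cfg$n_datasets),
                          ncol = 2L)
      reps <- replicate_table(cfg, rep_seeds, cutoff_rule)
      cbind(base,
            n_eval_a = as.integer(round(cfg$eval_fraction * na)),
            n_train_a = na - as.integer(round(cfg$eval_fraction * na)),
            auc_mean = mean(reps$auc), auc_sd = sd(reps$auc),
            acc_mean = mean(reps$accuracy), acc_sd = sd(reps$accuracy),
            youden_mean = mean(reps$youden), youden_sd = sd(reps$youden),
            beta0_mean = mean(reps$beta0), beta0_sd = sd(reps$beta0),
            beta1_mean = mean(reps$beta1), beta1_sd = sd(reps$beta1),
            valid = TRUE)
    }, error = function(e) {
      cbind(base, n_eval_a = NA_integer_, n_train_a = NA_integer_,
            auc_mean = NA_real_, auc_sd = NA_real_, acc_mean = NA_real_,
            acc_sd = NA_real_, youden_mean = NA_real_,
            youden_sd = NA_real_, beta0_mean = NA_real_,
            beta0_sd = NA_real_, beta1_mean = NA_real_,
            beta1_sd = NA_real_, valid = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fraction), ]
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Select the smallest adequate test-size fraction
#'
#' Applies the two-fold optimization criterion to a sorted sweep: pick
#' the smallest fraction whose mean AUC (i) changes by at most
#' `slope_tol` to the next larger fraction (a plateau has been reached;
#' the last fraction satisfies this vacuously) and (ii) stays above
#' `auc_floor` after subtracting one standard deviation.
#'
#' @param sweep A `"sweep_result"` from [sweep_test_size()] (invalid rows
#'   are dropped).
#' @param auc_floor Lower AUC bound after the SD subtraction
#'   (default 0.7).
#' @param slope_tol Maximum allowed change in mean AUC between adjacent
#'   fractions (default 0.01).
#' @return The selected fraction, or `NA` if none qualifies.
#' @export
select_optimal_fraction <- function(sweep, auc_floor = 0.7,
                                    slope_tol = 0.01) {
  if (!is.data.frame(sweep) ||
      !all(c("fraction", "auc_mean", "auc_sd") %in% names(sweep))) {
    stop_domain("'sweep' must be a sweep_result data frame")
  }
  s <- sweep[if ("valid" %in% names(sweep)) sweep$valid else TRUE, ,
             drop = FALSE]
  s <- s[order(s$fraction), , drop = FALSE]
  k <- nrow(s)
  if (k < 2L) stop_domain("need at least two valid fractions")
  for (i in seq_len(k)) {
    slope_ok <- if (i < k) {
      abs(s$auc_mean[i] - s$auc_mean[i + 1L]) <= slope_tol
    } else {
      TRUE
    }
    floor_ok <- (s$auc_mean[i] - s$auc_sd[i]) > auc_floor
    if (slope_ok && floor_ok) return(s$fraction[i])
  }
  NA_real_
}

#' Projected scan-time reduction from a test-size fraction
#'
#' Assuming scan time is linear in the number of sampled pores, using
#' fraction `f` of the full dataset reduces predicted AFM usage time by
#' `100 * (1 - f)` percent (30% at `f = 0.7`, 20% at `f = 0.8`).
#'
#' @param optimal_fraction Fraction in (0, 1].
#' @return Percent reduction.
#' @export
scan_time_reduction <- function(optimal_fraction) {
  if (any(!is.finite(optimal_fraction)) || any(optimal_fraction <= 0) ||
      any(optimal_fraction > 1)) {
    stop_domain("'optimal_fraction' must lie in (0, 1]")
  }
  100 * (1 - optimal_fraction)
}

#' Agreement between a raw-data AUC and the bootstrap aggregate
#'
#' Declares agreement when the raw-dataset AUC lies within
#' `k` standard deviations of the bootstrap mean AUC.
#'
#' @param raw_auc AUC computed on the raw (non-bootstrapped) dataset.
#' @param algo_mean,algo_sd Bootstrap mean and SD of the AUC.
#' @param k SD multiplier (default 2).
#' @return `TRUE` iff `|raw_auc - algo_mean| <= k * algo_sd`.
#' @examples
#' agreement_check(0.749, 0.7216, 0.0425) # TRUE
#' agreement_check(0.708, 0.6613, 0.0184) # FALSE
#' @export
agreement_check <- function(raw_auc, algo_mean, algo_sd, k = 2) {
  if (algo_sd < 0) stop_domain("'algo_sd' must be >= 0")
  if (k < 0) stop_domain("'k' must be >= 0")
  abs(raw_auc - algo_mean) <= k * algo_sd
}
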