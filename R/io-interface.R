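#' Read pore measurements from a delimited text file
#'
#' Expects a comma-delimited, UTF-8, header-first file with columns
#' `pore_radius_nm`, `mwco_kda`, `mode`, `location_id`,
#' `acquisition_index` ('.' decimal separator; radii strictly in nm).
#' Rows are grouped into one [pore_set()] per (MWCO, mode) combination.
#' Validation failures (missing column, non-numeric or non-positive
#' radius, duplicate acquisition index within a group) raise errors that
#' name the offending file line (the header is line 1).
#'
#' @param path Path to the CSV file.
#' @return Named list of `pore_set`s, names `"<mwco>kDa_<mode>"`, each
#'   ordered by acquisition index.
#' @seealso [write_measurements()]
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  required <- c("pore_radius_nm", "mwco_kda", "mode", "location_id",
                "acquisition_index")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_domain("missing column(s): ", paste(missing, collapse = ", "))
  }
  line_no <- seq_len(nrow(raw)) + 1L # header is line 1

  radius <- suppressWarnings(as.numeric(raw$pore_radius_nm))
  bad <- which(!is.finite(radius))
  if (length(bad) > 0) {
    stop_domain("non-numeric pore radius at line ", line_no[bad[1L]])
  }
  bad <- which(radius <= 0)
  if (length(bad) > 0) {
    stop_domain("non-positive pore radius at line ", line_no[bad[1L]])
  }
  mwco <- suppressWarnings(as.numeric(raw$mwco_kda))
  bad <- which(!is.finite(mwco) | mwco <= 0)
  if (length(bad) > 0) {
    stop_domain("invalid mwco_kda at line ", line_no[bad[1L]])
  }
  if (!all(raw$mode %in% c("tapping", "fluid"))) {
    bad <- which(!raw$mode %in% c("tapping", "fluid"))
    stop_domain("invalid mode at line ", line_no[bad[1L]],
                " (must be 'tapping' or 'fluid')")
  }
  acq <- suppressWarnings(as.integer(raw$acquisition_index))
  bad <- which(!is.finite(acq) | acq < 1L)
  if (length(bad) > 0) {
    stop_domain("invalid acquisition_index at line ", line_no[bad[1L]])
  }

  key <- paste0(mwco, "kDa_", raw$mode)
  dup <- duplicated(data.frame(key, acq))
  if (any(dup)) {
    stop_domain("duplicate (mwco, mode, acquisition_index) at line ",
                line_no[which(dup)[1L]])
  }

  sets <- lapply(split(seq_len(nrow(raw)), key), function(idx) {
    ord <- idx[order(acq[idx])]
    pore_set(radius[ord], mwco_kda = mwco[ord][1L], mode = raw$mode[ord][1L],
             location_ids = raw$location_id[ord],
             acquisition_index = acq[ord])
  })
  sets[unique(key)]
}

#' Write pore measurements to a delimited text file
#'
#' Inverse of [read_measurements()]: writes one row per pore with the
#' standard five columns. `read_measurements(write_measurements(x))`
#' reproduces `x`.
#'
#' @param sets A single [pore_set()] or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(sets, path) {
  if (inherits(sets, "pore_set")) sets <- list(sets)
  if (!all(vapply(sets, inherits, logical(1), "pore_set"))) {
    stop_domain("'sets' must be pore_set objects")
  }
  df <- do.call(rbind, lapply(sets, as.data.frame))
  write.csv(df, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Export ROC coordinates as delimited text
#'
#' Writes the per-cutoff operating points (`cutoff`, `sensitivity`,
#' `specificity`) of a [roc_curve()] for external plotting.
#'
#' @param roc A `"roc_curve"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  if (!inherits(roc, "roc_curve")) stop_domain("'roc' must be a roc_curve")
  write.csv(roc$points, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

fmt_num <- function(x, digits = 6) {
  formatC(x, digits = digits, format = "g")
}

#' Write the pipeline report files
#'
#' Emits the analysis tables as deterministic CSV/text files under
#' `dir`:
#' * `qc_table.csv` — per-dataset quality control (moments, JB, drift
#'   adjusted R-squared and flag, location-shift Kruskal–Wallis p), from
#'   `results$qc`;
#' * `discrimination_table.csv` — pairwise discrimination tests, from
#'   `results$discrimination`;
#' * `replicate_auc_table.csv` — per-pair bootstrap aggregates, from
#'   `results$pairs` (a named list of `"pair_classification"` objects),
#'   with the AUC strength category of the mean;
#' * `sweep_table.csv` plus `sweep_summary.txt` (selected fraction and
#'   projected scan-time reduction), from `results$sweep` and
#'   `results$optimal_fraction`;
#' * `roc_<name>.csv` for each entry of `results$rocs`.
#'
#' Sections whose inputs are absent are skipped with a message. Every
#' number written is taken from the supplied result objects; nothing is
#' recomputed here except the AUC category labels of reported means.
#'
#' @param results Named list with any of `qc`, `discrimination`, `pairs`,
#'   `sweep`, `optimal_fraction`, `rocs`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
run_report <- function(results, dir) {
  if (!is.list(results)) stop_domain("'results' must be a list")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    written <<- c(written, p)
  }

  if (!is.null(results$qc)) {
    emit(results$qc, "qc_table.csv")
  } else {
    message("run_report: no QC results; skipping qc_table.csv")
  }
  if (!is.null(results$discrimination)) {
    emit(results$discrimination, "discrimination_table.csv")
  } else {
    message("run_report: no discrimination results; skipping table")
  }
  if (!is.null(results$pairs)) {
    tab <- do.call(rbind, lapply(names(results$pairs), function(nm) {
      s <- results$pairs[[nm]]$summary
      cbind(data.frame(pair = nm), s,
            auc_category = auc_category(s$auc_mean))
    }))
    emit(tab, "replicate_auc_table.csv")
  } else {
    message("run_report: no pair results; skipping replicate_auc_table.csv")
  }
  if (!is.null(results$sweep) && nrow(results$sweep) > 0) {
    emit(as.data.frame(results$sweep), "sweep_table.csv")
    p <- file.path(dir, "sweep_summary.txt")
    lines <- if (!is.null(results$optimal_fraction) &&
                 is.finite(results$optimal_fraction)) {
      c(sprintf("optimal_fraction: %s", fmt_num(results$optimal_fraction)),
        sprintf("scan_time_reduction_percent: %s",
                fmt_num(scan_time_reduction(results$optimal_fraction))))
    } else {
      "optimal_fraction: none (no fraction met the selection criteria)"
    }
    writeLines(lines, p)
    written <- c(written, p)
  } else {
    message("run_report: no sweep results; skipping sweep section")
  }
  if (!is.null(results$rocs)) {
    for (nm in names(results$rocs)) {
      p <- file.path(dir, paste0("roc_", nm, ".csv"))
      write_roc(results$rocs[[nm]], p)
      written <- c(written, p)
    }
  }
  invisible(written)
}

#' Per-dataset quality-control summary
#'
#' Convenience builder for the QC table of [run_report()]: for each
#' measurement set it records the sample moments, the Jarque–Bera screen
#' (against a finite-sample critical value if supplied), the Fourier
#' drift fit (raw and robust adjusted R-squared, drift flag) and the
#' location-shift Kruskal–Wallis p-value.
#'
#' @param sets Named list of [pore_set()]s.
#' @param jb_critical_values Optional named/recycled vector of JB
#'   critical values (defaults to the asymptotic 5.99).
#' @param drift_threshold Threshold on adjusted R-squared for the drift
#'   flag (default 0.8).
#' @return Data frame, one row per set.
#' @export
qc_summary <- function(sets, jb_critical_values = NULL,
                       drift_threshold = 0.8) {
  if (inherits(sets, "pore_set")) sets <- list(sets)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  crit <- if (is.null(jb_critical_values)) {
    rep(qchisq(0.95, 2), length(sets))
  } else {
    rep_len(jb_critical_values, length(sets))
  }
  rows <- lapply(seq_along(sets), function(i) {
    ps <- sets[[i]]
    m <- sample_moments(ps$values)
    jb <- jarque_bera(m, crit[i])
    drift <- fit_fourier(ps, threshold = drift_threshold)
    drift_rob <- fit_fourier(ps, robust = TRUE,
                             threshold = drift_threshold)
    kw_p <- if (length(unique(ps$location_ids)) > 1L) {
      location_shift_test(ps)$p_value
    } else {
      NA_real_
    }
    data.frame(
      dataset = names(sets)[i], mwco_kda = ps$mwco_kda, mode = ps$mode,
      n = m$n, mean_nm = m$mean, skewness = m$skewness,
      kurtosis = m$kurtosis, jb_statistic = jb$statistic,
      jb_critical = jb$critical_value,
      passes_normality = jb$passes_normality,
      r2_adj_raw = drift$r2_adjusted, r2_adj_robust = drift_rob$r2_adjusted,
      drift_flag = drift_rob$drift_flag, kw_location_p = kw_p,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
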