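#' Labeled set of AFM pore-radius measurements
#'
#' A `pore_set` bundles the per-pore radii measured on one membrane in one
#' imaging mode together with the metadata the pipeline's quality-control
#' steps need: the membrane's molecular-weight-cutoff label, the imaging
#' mode, the scan location each pore came from, and the order in which the
#' pores were acquired.
#'
#' All radii are in nanometres and must be strictly positive. The
#' acquisition index is the only proxy for time available to the drift
#' detector, so it must be unique within a set.
#'
#' @param values Numeric vector of pore radii (nm), all `> 0`.
#' @param mwco_kda Molecular-weight cutoff label of the membrane, in kDa
#'   (the study membranes are 50, 100 and 1000, but any positive label is
#'   accepted).
#' @param mode Imaging mode, `"tapping"` or `"fluid"`.
#' @param location_ids Per-value scan-location labels (coerced to
#'   character). Defaults to a single location `"L1"`.
#' @param acquisition_index Per-value 1-based acquisition order; must be
#'   unique. Defaults to `seq_along(values)`.
#'
#' @return An object of class `"pore_set"`: a list with elements `values`,
#'   `mwco_kda`, `mode`, `location_ids`, `acquisition_index`.
#' @examples
#' ps <- pore_set(c(5.1, 7.9, 6.4, 8.8), mwco_kda = 1000, mode = "tapping",
#'                location_ids = c("L1", "L1", "L2", "L2"))
#' ps
#' @export
pore_set <- function(values, mwco_kda, mode = c("tapping", "fluid"),
                     location_ids = NULL, acquisition_index = NULL) {
  mode <- match.arg(mode)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1L) stop_domain("'values' must contain at least one radius")
  if (any(!is.finite(values))) stop_domain("pore radii must be finite")
  if (any(values <= 0)) stop_domain("pore radii must be strictly positive (nm)")
  if (!is.numeric(mwco_kda) || length(mwco_kda) != 1L || mwco_kda <= 0) {
    stop_domain("'mwco_kda' must be a single positive number")
  }
  if (is.null(location_ids)) location_ids <- rep("L1", n)
  location_ids <- as.character(location_ids)
  if (length(location_ids) != n) {
    stop_domain("'location_ids' must have one entry per value")
  }
  if (is.null(acquisition_index)) acquisition_index <- seq_len(n)
  acquisition_index <- as.integer(acquisition_index)
  if (length(acquisition_index) != n || anyNA(acquisition_index) ||
      any(acquisition_index < 1L) || anyDuplicated(acquisition_index)) {
    stop_domain("'acquisition_index' must be unique positive integers, one per value")
  }
  structure(
    list(values = values, mwco_kda = mwco_kda, mode = mode,
         location_ids = location_ids,
         acquisition_index = acquisition_index),
    class = "pore_set"
  )
}

#' @export
print.pore_set <- function(x, ...) {
  cat(sprintf("Pore measurement set: %g kDa, %s mode\n", x$mwco_kda, x$mode))
  cat(sprintf("  n = %d pores over %d scan location(s)\n",
              length(x$values), length(unique(x$location_ids))))
  cat(sprintf("  radius (nm): mean %.3g, range [%.3g, %.3g]\n",
              mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.pore_set <- function(x, ...) {
  data.frame(
    pore_radius_nm = x$values,
    mwco_kda = x$mwco_kda,
    mode = x$mode,
    location_id = x$location_ids,
    acquisition_index = x$acquisition_index,
    stringsAsFactors = FALSE
  )
}

# Accept either a pore_set or a bare numeric vector of radii.
pore_values <- function(x, arg = "x") {
  if (inherits(x, "pore_set")) return(x$values)
  if (is.numeric(x)) return(as.numeric(x))
  stop_domain("'", arg, "' must be a pore_set or a numeric vector")
}
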