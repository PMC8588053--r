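#' Configuration for a synthetic membrane dataset
#'
#' Describes one simulated AFM measurement series: iid Gamma pore radii
#' with optional perturbations — a sinusoidal drift over acquisition
#' order (positive control for [fit_fourier()]), per-location mean
#' offsets (positive control for [location_shift_test()]) and
#' multiplicative outliers.
#'
#' @param gamma A [gamma_params()] object for the base radii.
#' @param n Number of pores.
#' @param n_locations Number of scan locations; pores are assigned to
#'   locations as evenly as possible, in acquisition order.
#' @param seed Optional seed.
#' @param drift_amplitude Amplitude (nm) of the injected sinusoidal drift
#'   (default 0 = none).
#' @param drift_period Period of the drift in acquisition-index units.
#' @param location_shift Per-location additive offsets (nm); a single 0
#'   (default) or one value per location.
#' @param outlier_rate Probability that a pore is an outlier, in `[0, 1]`.
#' @param outlier_scale Multiplier applied to outlying pores (`> 0`).
#' @param mwco_kda,mode Metadata stamped on the generated [pore_set()].
#' @return Object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(gamma, n, n_locations = 1, seed = NULL,
                             drift_amplitude = 0, drift_period = NULL,
                             location_shift = 0, outlier_rate = 0,
                             outlier_scale = 1, mwco_kda = 100,
                             mode = c("tapping", "fluid")) {
  if (!inherits(gamma, "gamma_params")) {
    stop_domain("'gamma' must be a gamma_params object")
  }
  mode <- match.arg(mode)
  if (!is.numeric(n) || n < 1) stop_domain("'n' must be a positive count")
  if (!is.numeric(n_locations) || n_locations < 1 || n_locations > n) {
    stop_domain("'n_locations' must be between 1 and n")
  }
  if (drift_amplitude < 0) stop_domain("'drift_amplitude' must be >= 0")
  if (is.null(drift_period)) drift_period <- max(2, n / 3)
  if (drift_period < 2) stop_domain("'drift_period' must be at least 2")
  if (!length(location_shift) %in% c(1L, n_locations)) {
    stop_domain("'location_shift' must be length 1 or n_locations")
  }
  if (outlier_rate < 0 || outlier_rate > 1) {
    stop_domain("'outlier_rate' must be in [0, 1]")
  }
  if (outlier_scale <= 0) stop_domain("'outlier_scale' must be > 0")
  structure(
    list(gamma = gamma, n = as.integer(n),
         n_locations = as.integer(n_locations), seed = seed,
         drift_amplitude = drift_amplitude, drift_period = drift_period,
         location_shift = rep_len(location_shift, n_locations),
         outlier_rate = outlier_rate, outlier_scale = outlier_scale,
         mwco_kda = mwco_kda, mode = mode),
    class = "synthetic_config"
  )
}

#' Generate a synthetic membrane measurement set
#'
#' Draws `n` iid Gamma pore radii, then applies the configured
#' perturbations: additive sinusoidal drift
#' `amplitude * sin(2*pi*t/period)` over the acquisition index, additive
#' per-location offsets, and multiplicative outliers on a random subset.
#' Positivity is preserved by rejection: any pore whose perturbed radius
#' would be non-positive has its base Gamma draw resampled (never
#' truncated, so no point mass appears near zero).
#'
#' @param config A [synthetic_config()].
#' @return A [pore_set()].
#' @examples
#' cfg <- synthetic_config(gamma_params(0.75, 12.6), n = 60,
#'                         n_locations = 5, seed = 1, mwco_kda = 1000)
#' make_membrane_dataset(cfg)
#' @export
make_membrane_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop_domain("'config' must be a synthetic_config")
  }
  n <- config$n
  t <- seq_len(n)
  loc <- sort(rep_len(seq_len(config$n_locations), n))
  pert <- config$drift_amplitude * sin(2 * pi * t / config$drift_period) +
    config$location_shift[loc]

  values <- with_seed(config$seed, {
    v <- rgamma(n, shape = config$gamma$shape,
                scale = config$gamma$scale) + pert
    for (guard in seq_len(1000L)) {
      bad <- v <= 0
      if (!any(bad)) break
      v[bad] <- rgamma(sum(bad), shape = config$gamma$shape,
                       scale = config$gamma$scale) + pert[bad]
    }
    if (any(v <= 0)) {
      stop_domain("could not generate positive radii: perturbations ",
                  "overwhelm the base distribution")
    }
    if (config$outlier_rate > 0) {
      out <- runif(n) < config$outlier_rate
      v[out] <- v[out] * config$outlier_scale
    }
    v
  })

  pore_set(values, mwco_kda = config$mwco_kda, mode = config$mode,
           location_ids = paste0("L", loc), acquisition_index = t)
}

# Study conditions for the six membrane/mode presets: reported mean (nm)
# and skewness of the pore-radius distributions, with the sampling design
# (tapping: 60 pores over 5 locations; fluid: 304 pores over 4 locations).
preset_table <- function() {
  data.frame(
    preset = c("tapping_1000", "tapping_100", "tapping_50",
               "fluid_1000", "fluid_100", "fluid_50"),
    mode = rep(c("tapping", "fluid"), each = 3L),
    mwco_kda = rep(c(1000, 100, 50), 2L),
    n = rep(c(60L, 304L), each = 3L),
    n_locations = rep(c(5L, 4L), each = 3L),
    mean_nm = c(9.45, 7.34, 5.65, 15.3, 8.34, 11.1),
    skewness = c(2.314, 2.599, 2.069, 4.776, 2.833, 2.307),
    stringsAsFactors = FALSE
  )
}

#' Parameters of the six membrane/mode presets
#'
#' The study conditions the synthetic generator emulates: three MWCO
#' membranes (50, 100, 1000 kDa) imaged in tapping mode (60 pores over 5
#' scan locations) and fluid mode (304 pores over 4 locations), each with
#' the reported mean and skewness of its pore-radius distribution and the
#' Gamma shape/scale implied by [gamma_fit_moments()].
#'
#' @return Data frame with one row per preset: `preset`, `mode`,
#'   `mwco_kda`, `n`, `n_locations`, `mean_nm`, `skewness`, `shape`,
#'   `scale`.
#' @export
membrane_preset_params <- function() {
  tab <- preset_table()
  fits <- Map(gamma_fit_moments, tab$mean_nm, tab$skewness)
  tab$shape <- vapply(fits, `[[`, numeric(1), "shape")
  tab$scale <- vapply(fits, `[[`, numeric(1), "scale")
  tab
}

#' Six preset synthetic measurement sets
#'
#' Generates the six membrane/mode datasets of [membrane_preset_params()]
#' as [pore_set()] objects, using Gamma distributions matched to each
#' preset's mean and skewness. All perturbations are off: the presets are
#' clean right-skewed samples with the block structure of the real scans.
#' Each preset gets its own reproducible substream of `seed`.
#'
#' @param seed Master seed (default 1108).
#' @return Named list of six `pore_set`s (`tapping_1000`, `tapping_100`,
#'   `tapping_50`, `fluid_1000`, `fluid_100`, `fluid_50`).
#' @examples
#' sets <- membrane_presets()
#' sapply(sets, function(s) length(s$values))
#' @export
membrane_presets <- function(seed = 1108) {
  tab <- membrane_preset_params()
  seeds <- sub_seeds(seed, nrow(tab))
  sets <- lapply(seq_len(nrow(tab)), function(i) {
    cfg <- synthetic_config(
      gamma = gamma_params(tab$shape[i], tab$scale[i]),
      n = tab$n[i], n_locations = tab$n_locations[i], seed = seeds[i],
      mwco_kda = tab$mwco_kda[i], mode = tab$mode[i]
    )
    make_membrane_dataset(cfg)
  })
  names(sets) <- tab$preset
  sets
}

#' Inject sinusoidal drift into an existing measurement set
#'
#' Adds `amplitude * sin(2*pi*t/period)` to the radii in acquisition
#' order, preserving all metadata. Intended as a positive control for the
#' drift detector. Errors if the drift would push any radius non-positive
#' (use [make_membrane_dataset()] with `drift_amplitude` for
#' rejection-sampled generation instead).
#'
#' @param dataset A [pore_set()].
#' @param amplitude Drift amplitude (nm); 0 is a no-op.
#' @param period Drift period in acquisition-index units (`>= 2`).
#' @return A new `pore_set` with drifted values.
#' @export
inject_drift <- function(dataset, amplitude, period) {
  if (!inherits(dataset, "pore_set")) {
    stop_domain("'dataset' must be a pore_set")
  }
  if (period < 2) stop_domain("'period' must be at least 2")
  t <- dataset$acquisition_index
  v <- dataset$values + amplitude * sin(2 * pi * t / period)
  if (any(v <= 0)) {
    stop_domain("injected drift drives some radii non-positive")
  }
  pore_set(v, mwco_kda = dataset$mwco_kda, mode = dataset$mode,
           location_ids = dataset$location_ids, acquisition_index = t)
}
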