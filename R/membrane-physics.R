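#' Theoretical Stokes radius of a solute from its molecular weight
#'
#' Models the solute (and hence the nominal membrane pore) as a solid
#' sphere of the solid-phase density, so that the sphere radius follows
#' from the mass of a single molecule:
#' \deqn{r_p = \left(\frac{3 M_w}{4 \rho \pi N_A}\right)^{1/3}}
#' with \eqn{M_w} in g/mol, \eqn{\rho} in g/cm^3 and \eqn{N_A} Avogadro's
#' number. The result is converted from cm to nm. This is the theoretical
#' reference radius against which AFM pore measurements are compared; for
#' the 50/100/1000 kDa membranes it gives 2.7/3.4/7.3 nm.
#'
#' @param molecular_weight Molecular weight in g/mol (use [kda()] to
#'   convert from kDa). May be a vector.
#' @param density Solute density in g/cm^3; default 1.
#' @param avogadro Avogadro constant (1/mol).
#' @return Stokes radius in nm (vectorized over `molecular_weight`).
#' @examples
#' round(stokes_radius(kda(c(50, 100, 1000))), 1) # 2.7 3.4 7.3
#' @export
stokes_radius <- function(molecular_weight, density = 1,
                          avogadro = 6.02214076e23) {
  if (any(!is.finite(molecular_weight)) || any(molecular_weight <= 0)) {
    stop_domain("'molecular_weight' must be positive and finite (g/mol)")
  }
  if (!is.finite(density) || density <= 0) {
    stop_domain("'density' must be a positive number (g/cm^3)")
  }
  r_cm <- (3 * molecular_weight / (4 * density * pi * avogadro))^(1 / 3)
  r_cm * 1e7 # cm -> nm
}

#' Convert kDa to g/mol
#'
#' @param x Molecular weight(s) in kDa.
#' @return The same weight(s) in g/mol.
#' @examples kda(100) # 1e5 g/mol
#' @export
kda <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_domain("molecular weight in kDa must be positive and finite")
  }
  x * 1000
}

#' Measurement-accuracy errors against the theoretical radius
#'
#' Relative (%) and absolute (nm) deviation of a measured mean pore radius
#' from the theoretical Stokes-radius reference. Values are carried at full
#' precision; display rounding (3 significant figures for the relative
#' error, whole nm for the absolute error) happens only in the print
#' method, matching the reporting convention of the pipeline.
#'
#' @param measured_mean Measured mean pore radius (nm), `>= 0`.
#' @param reference_radius Theoretical reference radius (nm), `> 0`.
#' @return Object of class `"accuracy_errors"` with elements
#'   `relative_percent` and `absolute_nm` (full precision).
#' @examples
#' accuracy_errors(15.3, 7.3) # ~110 %, ~8 nm
#' @export
accuracy_errors <- function(measured_mean, reference_radius) {
  if (!is.finite(reference_radius) || reference_radius <= 0) {
    stop_domain("'reference_radius' must be a positive number (nm)")
  }
  if (!is.finite(measured_mean) || measured_mean < 0) {
    stop_domain("'measured_mean' must be a non-negative number (nm)")
  }
  abs_nm <- abs(measured_mean - reference_radius)
  structure(
    list(relative_percent = 100 * abs_nm / reference_radius,
         absolute_nm = abs_nm,
         measured_mean = measured_mean,
         reference_radius = reference_radius),
    class = "accuracy_errors"
  )
}

#' @export
print.accuracy_errors <- function(x, ...) {
  cat(sprintf("Accuracy error vs. reference %.3g nm:\n", x$reference_radius))
  cat(sprintf("  relative: %s %%\n", format(signif(x$relative_percent, 3))))
  cat(sprintf("  absolute: %d nm\n", round(x$absolute_nm)))
  invisible(x)
}

#' Absolute accuracy error across hypothetical swelling ratios
#'
#' Cellulose hydrogels swell in solution; if the true pore radius is the
#' dry theoretical radius scaled by `(1 + SR)` for a swelling ratio SR,
#' the measurement error becomes `|measured - reference * (1 + SR)|`.
#' Scanning a grid of SR values shows whether a single hydration state can
#' reconcile measured and theoretical radii. The error is V-shaped in SR
#' with its continuous minimum at `SR* = measured/reference - 1`.
#'
#' @param measured_mean Measured mean radius (nm).
#' @param reference_radius Theoretical (dry) reference radius (nm), `> 0`.
#' @param sr_grid Vector of non-negative swelling ratios, as fractions
#'   (e.g. 0.5 for 50 %, 2 for 200 %).
#' @return Object of class `"swelling_scan"`: a data frame with columns
#'   `sr`, `adjusted_radius`, `abs_error`, plus attributes `sr_opt` (grid
#'   minimizer) and `sr_star` (continuous minimizer).
#' @examples
#' sc <- swelling_error_scan(11.1, 2.7, seq(0.5, 2, by = 0.25))
#' sc[sc$sr == 2, ] # abs_error 3 nm at SR = 200 %
#' @export
swelling_error_scan <- function(measured_mean, reference_radius, sr_grid) {
  if (!is.finite(reference_radius) || reference_radius <= 0) {
    stop_domain("'reference_radius' must be a positive number (nm)")
  }
  if (length(sr_grid) == 0) stop_domain("'sr_grid' must be non-empty")
  if (any(!is.finite(sr_grid)) || any(sr_grid < 0)) {
    stop_domain("swelling ratios must be finite and >= 0")
  }
  adjusted <- reference_radius * (1 + sr_grid)
  err <- abs(measured_mean - adjusted)
  out <- data.frame(sr = sr_grid, adjusted_radius = adjusted,
                    abs_error = err)
  attr(out, "sr_opt") <- sr_grid[which.min(err)]
  attr(out, "sr_star") <- measured_mean / reference_radius - 1
  class(out) <- c("swelling_scan", "data.frame")
  out
}
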