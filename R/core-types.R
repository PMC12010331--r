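# Domain containers for spectro-temporal data.
#
# Conventions used throughout the package:
#   * time is in picoseconds, t = 0 at the instrument-response (IRF) center;
#     negative delays (pre-excitation baseline) are permitted,
#   * wavelengths are in nanometres, ascending,
#   * differential absorbance is stored in mOD.

#' Wavelength x delay differential-absorbance matrix
#'
#' The central container of the package: a pump-probe surface
#' \eqn{\Delta A(\lambda, t)} on a strictly increasing wavelength axis (nm)
#' and a strictly increasing delay axis (ps), with values in mOD indexed
#' `[delay, wavelength]`.
#'
#' @param wavelengths numeric, nm, strictly increasing.
#' @param delays numeric, ps, strictly increasing; t = 0 is the IRF center.
#' @param values numeric matrix, mOD, dimensions
#'   `length(delays) x length(wavelengths)`.
#' @param pump_nm optional pump wavelength, nm.
#' @param label optional free-text label.
#' @return An object of class `spectral_time_matrix`.
#' @export
spectral_time_matrix <- function(wavelengths, delays, values,
                                 pump_nm = NULL, label = "") {
  wavelengths <- as.numeric(wavelengths)
  delays <- as.numeric(delays)
  values <- as.matrix(values)
  tag_assert(all(is.finite(wavelengths)) && all(is.finite(delays)),
             "axes must be finite")
  tag_assert(!anyNA(values) && all(is.finite(values)),
             "values must be finite")
  tag_assert(all(diff(wavelengths) > 0),
             "wavelength axis must be strictly increasing",
             "tag_duplicate_axis_error")
  tag_assert(all(diff(delays) > 0),
             "delay axis must be strictly increasing",
             "tag_duplicate_axis_error")
  tag_assert(all(dim(values) == c(length(delays), length(wavelengths))),
             sprintf("values must be %d x %d (delay x wavelength), got %d x %d",
                     length(delays), length(wavelengths),
                     nrow(values), ncol(values)))
  structure(list(wavelengths = wavelengths, delays = delays,
                 values = unname(values), pump_nm = pump_nm,
                 label = as.character(label)),
            class = "spectral_time_matrix")
}

#' @export
print.spectral_time_matrix <- function(x, ...) {
  cat(sprintf(
    "<spectral_time_matrix> %d delays x %d wavelengths\n", length(x$delays),
    length(x$wavelengths)))
  cat(sprintf("  wavelengths: %.1f .. %.1f nm\n",
              min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  delays:      %.4g .. %.4g ps\n", min(x$delays), max(x$delays)))
  cat(sprintf("  dA range:    %.4g .. %.4g mOD\n",
              min(x$values), max(x$values)))
  if (!is.null(x$pump_nm)) cat(sprintf("  pump:        %.0f nm\n", x$pump_nm))
  if (nzchar(x$label)) cat(sprintf("  label:       %s\n", x$label))
  invisible(x)
}

#' Single spectrum
#'
#' A one-dimensional spectrum (steady-state absorbance or a difference
#' spectrum) on a wavelength axis.
#'
#' @param wavelengths numeric, nm.
#' @param values numeric, same length; OD or mOD depending on use.
#' @param label optional free-text label.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, values, label = "") {
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  tag_assert(length(wavelengths) == length(values),
             "wavelengths and values must have equal length")
  tag_assert(all(is.finite(wavelengths)) && all(is.finite(values)),
             "spectrum must be finite")
  structure(list(wavelengths = wavelengths, values = values,
                 label = as.character(label)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.1f .. %.1f nm%s\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              if (nzchar(x$label)) paste0(", ", x$label) else ""))
  invisible(x)
}

#' Gaussian instrument-response model
#'
#' The instrument response function (IRF) of both the pump-probe and the
#' fluorescence experiments is modelled as a Gaussian of full width at half
#' maximum `fwhm` centered at `t0`. The standard deviation is
#' \eqn{\sigma = \mathrm{fwhm} / (2\sqrt{2\ln 2})}.
#'
#' @param t0 center (time zero), ps.
#' @param fwhm full width at half maximum, ps; must be positive.
#' @return An object of class `irf_model` with fields `t0`, `fwhm`, `sigma`.
#' @export
irf_model <- function(t0 = 0, fwhm = 0.1) {
  tag_assert(is.finite(t0) && is.finite(fwhm) && fwhm > 0,
             "irf fwhm must be positive and finite")
  structure(list(t0 = as.numeric(t0), fwhm = as.numeric(fwhm),
                 sigma = as.numeric(fwhm) / (2 * sqrt(2 * log(2)))),
            class = "irf_model")
}

#' @export
print.irf_model <- function(x, ...) {
  cat(sprintf("<irf_model> t0 = %.4g ps, fwhm = %.4g ps (sigma %.4g ps)\n",
              x$t0, x$fwhm, x$sigma))
  invisible(x)
}

#' Analysis configuration
#'
#' Collects the tunable constants of the analysis chain in one validated
#' object: the lifetime-grid bounds and density for the maximum-entropy
#' lifetime distribution analysis, the entropy prior scale, the
#' regularization scan, IRF defaults, the dynamical floor below which
#' lifetime peaks are attributed to the coherent artifact, and the seed.
#'
#' @param tau_min,tau_max lifetime-grid bounds, ps.
#' @param points_per_decade lifetime-grid density (>= 1).
#' @param entropy_prior_frac entropy prior scale m as a fraction of the
#'   per-wavelength maximum |dA|.
#' @param n_alpha,alpha_decades regularization scan: number of log-spaced
#'   candidates and the number of decades spanned.
#' @param irf_fwhm default Gaussian IRF full width at half maximum, ps.
#' @param floor_ps lifetime floor, ps: dynamical-content peaks at or below
#'   this lifetime are discarded as coherent-artifact/cross-phase-modulation
#'   events.
#' @param seed integer random seed.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(tau_min = 0.02, tau_max = 1000,
                            points_per_decade = 20,
                            entropy_prior_frac = 0.01,
                            n_alpha = 25, alpha_decades = 6,
                            irf_fwhm = 0.1, floor_ps = 0.15, seed = 1L) {
  tag_assert(tau_min > 0 && tau_max > tau_min,
             "lifetime bounds must satisfy 0 < tau_min < tau_max")
  tag_assert(points_per_decade >= 1, "points_per_decade must be >= 1")
  tag_assert(floor_ps >= 0, "floor_ps must be >= 0")
  tag_assert(entropy_prior_frac > 0, "entropy_prior_frac must be > 0")
  tag_assert(n_alpha >= 5, "n_alpha must be >= 5")
  tag_assert(irf_fwhm > 0, "irf_fwhm must be > 0")
  structure(list(tau_min = tau_min, tau_max = tau_max,
                 points_per_decade = points_per_decade,
                 entropy_prior_frac = entropy_prior_frac,
                 n_alpha = n_alpha, alpha_decades = alpha_decades,
                 irf_fwhm = irf_fwhm, floor_ps = floor_ps,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Per-component spectra (DADS or EADS)
#'
#' A set of component spectra sharing one wavelength axis, each tagged with
#' a lifetime. `kind = "DADS"` are decay-associated difference spectra
#' (amplitudes of a parallel multiexponential decomposition);
#' `kind = "EADS"` are evolution-associated difference spectra (species
#' spectra of a sequential irreversible scheme).
#'
#' @param kind `"DADS"` or `"EADS"`.
#' @param lifetimes numeric, ps, one per component.
#' @param wavelengths shared wavelength axis, nm.
#' @param spectra numeric matrix `[wavelength, component]`, mOD.
#' @return An object of class `component_spectra`.
#' @export
component_spectra <- function(kind, lifetimes, wavelengths, spectra) {
  kind <- match.arg(kind, c("DADS", "EADS"))
  spectra <- as.matrix(spectra)
  tag_assert(length(lifetimes) == ncol(spectra),
             "one spectrum per lifetime required")
  tag_assert(nrow(spectra) == length(wavelengths),
             "spectra rows must match wavelength axis")
  tag_assert(all(lifetimes > 0), "lifetimes must be positive")
  structure(list(kind = kind, lifetimes = as.numeric(lifetimes),
                 wavelengths = as.numeric(wavelengths),
                 spectra = unname(spectra)),
            class = "component_spectra")
}

#' @export
print.component_spectra <- function(x, ...) {
  cat(sprintf("<component_spectra> %s, %d components (tau = %s ps)\n",
              x$kind, length(x$lifetimes),
              paste(signif(x$lifetimes, 3), collapse = ", ")))
  invisible(x)
}

axes_equal <- function(a, b, tol = 1e-6) {
  length(a) == length(b) && all(abs(a - b) <= tol)
}
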