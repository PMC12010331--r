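# Corrections applied before kinetic analysis: supercontinuum chirp
# estimation/correction, solvent/background subtraction, logarithmic time
# averaging and pre-excitation baseline noise estimation.

#' Estimate the supercontinuum chirp
#'
#' Estimates the per-wavelength time zero t0(lambda) from the squared
#' time-derivative of the signal: the signal rise contributes a squared
#' slope symmetric about t0 (the Gaussian IRF edge), and a coherent
#' artifact contributes a two-lobed but equally symmetric squared slope,
#' so the slope-squared centroid in a local window around the maximum-
#' |slope| point estimates t0 without bias for either feature. A cubic
#' polynomial in the normalized wavelength is then fit by least squares.
#'
#' @param matrix a [spectral_time_matrix()] with delays bracketing t = 0.
#' @param window_ps half-width of the search window around zero, ps.
#' @param local_ps half-width of the slope-squared centroid window around
#'   the maximum-|slope| delay, ps; should cover the IRF and artifact
#'   lobes.
#' @param degree polynomial degree of the dispersion curve.
#' @return list of class `chirp_curve`: `coefficients` (lowest order
#'   first, in u = (lambda - min)/(max - min)), `t0` (per-wavelength
#'   estimates, ps), `fitted_t0`, `rms_residual_ps`, `wavelengths`.
#' @export
estimate_chirp <- function(matrix, window_ps = 1, local_ps = 0.25,
                           degree = 3) {
  stopifnot(inherits(matrix, "spectral_time_matrix"))
  if (!any(matrix$delays < 0))
    tag_stop("no pre-zero delays: cannot locate time zero",
             "tag_insufficient_baseline_error")
  t <- matrix$delays
  inwin <- which(abs(t) <= window_ps)
  tag_assert(length(inwin) >= 4, "too few delays in the time-zero window",
             "tag_insufficient_baseline_error")
  tw <- t[inwin]
  nw <- length(inwin)
  # central differences over a ~3-step stencil: tames the slope-squared
  # noise floor at 20 fs sampling while still resolving a >= 50 fs IRF edge
  k <- min(3, (nw - 1) %/% 2)
  ctr <- (1 + k):(nw - k)
  tmid <- tw[ctr]
  est <- vapply(seq_along(matrix$wavelengths), function(j) {
    col <- matrix$values[inwin, j]
    sl2 <- ((col[ctr + k] - col[ctr - k]) / (tw[ctr + k] - tw[ctr - k]))^2
    sl2 <- pmax(sl2 - stats::median(sl2), 0)  # remove the noise floor
    i <- which.max(sl2)
    loc <- abs(tmid - tmid[i]) <= local_ps
    if (sum(sl2[loc]) == 0) return(c(tmid[i], 0))
    c(sum(tmid[loc] * sl2[loc]) / sum(sl2[loc]), sum(sl2[loc]))
  }, numeric(2))
  t0 <- est[1, ]
  u <- (matrix$wavelengths - min(matrix$wavelengths)) /
    max(diff(range(matrix$wavelengths)), 1)
  # weight by each column's slope power: the dispersion curve is smooth, so
  # signal-free columns (whose marker is noise) should not drag the fit
  fit <- stats::lm(t0 ~ stats::poly(u, degree = degree, raw = TRUE),
                   weights = est[2, ])
  structure(list(coefficients = unname(stats::coef(fit)),
                 t0 = t0, fitted_t0 = unname(stats::fitted(fit)),
                 rms_residual_ps = sqrt(mean(stats::resid(fit)^2)),
                 wavelengths = matrix$wavelengths),
            class = "chirp_curve")
}

#' Correct a matrix for supercontinuum chirp
#'
#' Re-interpolates each wavelength column (linearly) onto the common delay
#' axis shifted by -t0(lambda), so every wavelength shares t = 0. Delays
#' shifted outside the measured range are filled with the column's
#' pre-zero baseline mean.
#'
#' @param matrix a [spectral_time_matrix()].
#' @param curve a `chirp_curve` from [estimate_chirp()], or a numeric
#'   vector of polynomial coefficients.
#' @return A chirp-corrected [spectral_time_matrix()].
#' @export
apply_chirp <- function(matrix, curve) {
  stopifnot(inherits(matrix, "spectral_time_matrix"))
  coefs <- if (inherits(curve, "chirp_curve")) curve$coefficients else
    as.numeric(curve)
  tag_assert(all(is.finite(coefs)), "chirp coefficients must be finite")
  t0 <- chirp_t0(coefs, matrix$wavelengths)
  t <- matrix$delays
  vals <- matrix$values
  out <- vals
  for (j in seq_along(matrix$wavelengths)) {
    if (t0[j] == 0) next
    base <- if (any(t < 0)) mean(vals[t < 0, j]) else vals[1, j]
    out[, j] <- stats::approx(t - t0[j], vals[, j], xout = t,
                              rule = 1)$y
    out[is.na(out[, j]), j] <- base
  }
  spectral_time_matrix(matrix$wavelengths, t, out,
                       pump_nm = matrix$pump_nm, label = matrix$label)
}

#' Subtract a reference (solvent/background) measurement
#'
#' Elementwise subtraction of a reference matrix measured on identical
#' axes, e.g. the pure-solvent response.
#'
#' @param matrix,reference [spectral_time_matrix()] objects on identical
#'   axes.
#' @return A [spectral_time_matrix()].
#' @export
subtract_reference <- function(matrix, reference) {
  stopifnot(inherits(matrix, "spectral_time_matrix"),
            inherits(reference, "spectral_time_matrix"))
  tag_assert(axes_equal(matrix$wavelengths, reference$wavelengths) &&
               axes_equal(matrix$delays, reference$delays),
             "matrix and reference axes differ", "tag_axis_mismatch_error")
  spectral_time_matrix(matrix$wavelengths, matrix$delays,
                       matrix$values - reference$values,
                       pump_nm = matrix$pump_nm, label = matrix$label)
}

#' Logarithmic time averaging
#'
#' Keeps delays up to `t_linear` as measured and bins later delays into
#' log-uniform bins (`points_per_decade` per decade, anchored at
#' `t_linear`). Each output row is the arithmetic mean of its member rows;
#' the output delay is the geometric mean of the member delays. Empty bins
#' are dropped. Data already log-spaced at the target density pass through
#' unchanged.
#'
#' @param matrix a [spectral_time_matrix()].
#' @param points_per_decade bin density (>= 1).
#' @param t_linear ps; delays `<= t_linear` are kept as-is.
#' @return A [spectral_time_matrix()].
#' @export
log_average <- function(matrix, points_per_decade = 20, t_linear = 0.5) {
  stopifnot(inherits(matrix, "spectral_time_matrix"))
  tag_assert(points_per_decade >= 1, "points_per_decade must be >= 1")
  t <- matrix$delays
  keep <- t <= t_linear * (1 + 1e-12)
  late <- which(!keep)
  if (length(late) == 0) return(matrix)
  idx <- round(points_per_decade * log10(t[late] / t_linear))
  groups <- split(late, idx)
  new_t <- vapply(groups, function(g) exp(mean(log(t[g]))), numeric(1))
  new_v <- t(vapply(groups, function(g)
    colMeans(matrix$values[g, , drop = FALSE]),
    numeric(length(matrix$wavelengths))))
  ord <- order(new_t)
  spectral_time_matrix(matrix$wavelengths,
                       c(t[keep], new_t[ord]),
                       rbind(matrix$values[keep, , drop = FALSE],
                             new_v[ord, , drop = FALSE]),
                       pump_nm = matrix$pump_nm, label = matrix$label)
}

#' Baseline noise estimate from pre-excitation delays
#'
#' Per-wavelength sample standard deviation over the delays earlier than
#' `-2 * irf_fwhm` (safely before the excitation edge), floored at 1e-6
#' mOD. These sigmas weight the chi-squared of both the lifetime
#' distribution analysis and the global kinetic fit.
#'
#' @param matrix a [spectral_time_matrix()].
#' @param irf_fwhm IRF full width at half maximum, ps; rows with
#'   `t < -2 * irf_fwhm` are treated as baseline.
#' @return numeric vector of per-wavelength sds, mOD.
#' @export
estimate_noise <- function(matrix, irf_fwhm = 0.1) {
  stopifnot(inherits(matrix, "spectral_time_matrix"))
  rows <- matrix$delays < -2 * irf_fwhm
  if (sum(rows) < 5)
    tag_stop(sprintf(
      "need >= 5 delays before %.3g ps for baseline noise (found %d)",
      -2 * irf_fwhm, sum(rows)), "tag_insufficient_baseline_error")
  pmax(apply(matrix$values[rows, , drop = FALSE], 2, stats::sd), 1e-6)
}
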