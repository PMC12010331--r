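# Synthetic transient-absorption matrices and fluorescence decays with the
# statistical structure the analysis assumes: multiexponential kinetics
# convolved with a Gaussian IRF, band-structured component spectra,
# supercontinuum chirp, a coherent artifact near time zero, and noise.
# Every downstream stage is testable on these without any instrument data.

#' Pump-probe delay grid: linear through the IRF, logarithmic after
#'
#' Builds the acquisition-style delay axis: linear steps of `step_fs`
#' within `[-irf_window_ps, +irf_window_ps]`, then logarithmically spaced
#' points (`points_per_decade` per decade, anchored at the window edge) out
#' to `t_max_ps`. Strictly increasing and deduplicated.
#'
#' @param step_fs linear step, fs (> 0).
#' @param irf_window_ps half-width of the linear window around t = 0, ps.
#' @param t_max_ps last delay, ps (>= window edge).
#' @param points_per_decade density of the logarithmic part.
#' @return numeric vector of delays, ps.
#' @export
make_time_grid <- function(step_fs = 20, irf_window_ps = 0.5,
                           t_max_ps = 1000, points_per_decade = 20) {
  tag_assert(step_fs > 0 && irf_window_ps > 0 && points_per_decade > 0,
             "grid parameters must be positive")
  tag_assert(t_max_ps >= irf_window_ps, "t_max_ps must be >= window edge")
  step <- step_fs * 1e-3
  lin <- seq(-irf_window_ps, irf_window_ps, by = step)
  if (t_max_ps > irf_window_ps * (1 + 1e-12)) {
    jmax <- floor(points_per_decade * log10(t_max_ps / irf_window_ps) +
                    1e-9)
    logp <- irf_window_ps * 10^(seq_len(jmax) / points_per_decade)
    logp <- logp[logp <= t_max_ps * (1 + 1e-12)]
  } else logp <- numeric(0)
  grid <- sort(unique(c(lin, logp)))
  grid[c(TRUE, diff(grid) > 1e-12)]
}

#' Sum-of-Gaussians band spectrum
#'
#' Builds a spectrum as a sum of Gaussian bands, the phenomenological
#' shapes of ground-state bleach (negative amplitude) and excited-state
#' absorption (positive amplitude) features.
#'
#' @param wavelengths axis, nm.
#' @param bands list of `c(center_nm, fwhm_nm, amplitude_mOD)` triples (or
#'   a 3-column matrix).
#' @return A [spectrum()].
#' @export
gaussian_band_spectrum <- function(wavelengths, bands) {
  if (is.list(bands)) bands <- do.call(rbind, bands)
  bands <- matrix(as.numeric(bands), ncol = 3)
  tag_assert(all(bands[, 2] > 0), "band fwhm must be positive")
  v <- rep(0, length(wavelengths))
  for (i in seq_len(nrow(bands))) {
    s <- bands[i, 2] / (2 * sqrt(2 * log(2)))
    v <- v + bands[i, 3] * exp(-(wavelengths - bands[i, 1])^2 / (2 * s^2))
  }
  spectrum(wavelengths, v)
}

#' Simulation specification for a transient-absorption measurement
#'
#' @param components list of components, each `list(lifetime = ps,
#'   spectrum = [spectrum()])`; spectra may be signed (bleach vs ESA).
#' @param irf an [irf_model()].
#' @param model `"parallel"` (each component decays independently; the
#'   spectra are the ground-truth DADS) or `"sequential"` (spectra are the
#'   EADS of the irreversible chain).
#' @param chirp_poly polynomial coefficients of t0(lambda), ps, in the
#'   normalized wavelength u = (lambda - min)/(max - min), lowest order
#'   first.
#' @param artifact_amp coherent-artifact amplitude at time zero, mOD.
#' @param artifact_width coherent-artifact Gaussian sigma, ps.
#' @param noise_sd additive Gaussian noise sd, mOD; either a scalar
#'   (homoscedastic) or one value per wavelength.
#' @param seed integer seed; all randomness of [simulate_ta()] flows from it.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(components, irf = irf_model(fwhm = 0.1),
                            model = c("parallel", "sequential"),
                            chirp_poly = 0, artifact_amp = 0,
                            artifact_width = 0.04, noise_sd = 0,
                            seed = 1L) {
  model <- match.arg(model)
  tag_assert(length(components) >= 1, "need at least one component")
  for (cmp in components) {
    tag_assert(is.finite(cmp$lifetime) && cmp$lifetime > 0,
               "component lifetimes must be positive")
    stopifnot(inherits(cmp$spectrum, "spectrum"))
  }
  tag_assert(all(noise_sd >= 0), "noise_sd must be >= 0")
  structure(list(components = components, irf = irf, model = model,
                 chirp_poly = as.numeric(chirp_poly),
                 artifact_amp = artifact_amp,
                 artifact_width = artifact_width,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_spec")
}

# t0(lambda) from the chirp polynomial in normalized wavelength.
chirp_t0 <- function(chirp_poly, wavelengths) {
  u <- (wavelengths - min(wavelengths)) /
    max(max(wavelengths) - min(wavelengths), 1)
  drop(outer(u, seq_along(chirp_poly) - 1, "^") %*% chirp_poly)
}

#' Simulate a transient-absorption matrix
#'
#' Forward model of the analysis chain:
#' \deqn{\Delta A(\lambda, t) = \sum_k S_k(\lambda)\, c_k(t - t_0(\lambda))
#'   + \mathrm{artifact}(\lambda, t) + \mathrm{noise},}
#' where the kinetic profiles \eqn{c_k} are Gaussian-IRF-convolved
#' exponentials (parallel model) or sequential-scheme concentrations, the
#' per-wavelength time zero \eqn{t_0(\lambda)} follows the chirp
#' polynomial, the coherent artifact is a Gaussian in time centered at
#' \eqn{t_0(\lambda)}, and the noise is i.i.d. Gaussian from the spec's
#' seed. Deterministic given the seed.
#'
#' @param spec a [simulation_spec()].
#' @param wavelengths axis, nm (defaults to the component spectra's axis).
#' @param delays axis, ps (defaults to [make_time_grid()] defaults).
#' @return A [spectral_time_matrix()].
#' @export
simulate_ta <- function(spec, wavelengths = NULL, delays = make_time_grid()) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(wavelengths))
    wavelengths <- spec$components[[1]]$spectrum$wavelengths
  nl <- length(wavelengths); nt <- length(delays)
  taus <- vapply(spec$components, `[[`, numeric(1), "lifetime")
  smat <- vapply(spec$components, function(cmp) {
    tag_assert(axes_equal(cmp$spectrum$wavelengths, wavelengths),
               "component spectra must share the simulation wavelength axis",
               "tag_axis_mismatch_error")
    cmp$spectrum$values
  }, numeric(nl))                                  # [wavelength, component]
  t0 <- chirp_t0(spec$chirp_poly, wavelengths)
  vals <- matrix(0, nt, nl)
  for (j in seq_len(nl)) {
    tj <- delays - t0[j]
    conc <- if (spec$model == "parallel") {
      conv_basis(tj, taus, spec$irf)
    } else {
      sequential_concentrations(taus, spec$irf, tj)$c
    }
    vals[, j] <- conc %*% smat[j, ]
    if (spec$artifact_amp != 0)
      vals[, j] <- vals[, j] + spec$artifact_amp *
        exp(-(tj - spec$irf$t0)^2 / (2 * spec$artifact_width^2))
  }
  if (any(spec$noise_sd > 0)) {
    sd_col <- rep(spec$noise_sd, length.out = nl)
    vals <- vals + withr::with_seed(
      spec$seed,
      matrix(stats::rnorm(nt * nl), nt, nl) %*% diag(sd_col, nl))
  }
  spectral_time_matrix(wavelengths, delays, vals, label = "synthetic")
}

#' Preset emulating a flavocytochrome-style two-component measurement
#'
#' A ready-made [simulation_spec()] with the qualitative structure of a
#' broadband visible pump-probe experiment on a flavohemoprotein: 80 probe
#' wavelengths spanning 290-1000 nm; a fast internal-conversion component
#' whose spectrum pairs a ground-state-bleach trough near 410 nm with
#' excited-state absorption near 420 and 700 nm; a slower
#' vibrational-cooling component with a narrower derivative-shaped 410/425
#' nm pair; a 0.10 ps FWHM Gaussian IRF; and additive noise scaled to the
#' clean-signal peak. The band shapes are qualitative test structure, not
#' measured amplitudes.
#'
#' @param lifetimes the two lifetimes, ps (fast, slow).
#' @param noise_frac noise sd as a fraction of the peak |dA| of the clean
#'   signal.
#' @param chirp_poly,artifact_amp chirp polynomial (ps, normalized
#'   wavelength) and coherent-artifact amplitude (mOD); both off by
#'   default.
#' @param irf_fwhm Gaussian IRF FWHM, ps.
#' @param n_wavelengths number of probe wavelengths across 290-1000 nm.
#' @param seed integer seed.
#' @return A [simulation_spec()].
#' @export
fcc_like_spec <- function(lifetimes = c(0.4, 4.3), noise_frac = 0.02,
                          chirp_poly = 0, artifact_amp = 0,
                          irf_fwhm = 0.1, n_wavelengths = 80, seed = 1L) {
  tag_assert(length(lifetimes) == 2 && all(lifetimes > 0),
             "preset takes two positive lifetimes")
  wl <- seq(290, 1000, length.out = n_wavelengths)
  s1 <- gaussian_band_spectrum(wl, list(c(410, 28, -6), c(432, 30, 3.5),
                                        c(700, 90, 2)))
  s2 <- gaussian_band_spectrum(wl, list(c(408, 22, -4), c(430, 26, 4)))
  comps <- list(list(lifetime = lifetimes[1], spectrum = s1),
                list(lifetime = lifetimes[2], spectrum = s2))
  # scale noise to the clean peak so noise_frac means "fraction of peak"
  clean <- simulate_ta(
    simulation_spec(comps, irf = irf_model(fwhm = irf_fwhm),
                    chirp_poly = chirp_poly, artifact_amp = artifact_amp,
                    noise_sd = 0, seed = seed),
    wavelengths = wl)
  simulation_spec(comps, irf = irf_model(fwhm = irf_fwhm),
                  chirp_poly = chirp_poly, artifact_amp = artifact_amp,
                  noise_sd = noise_frac * max(abs(clean$values)),
                  seed = seed)
}

#' Simulate a fluorescence decay with Poisson counting noise
#'
#' Expected counts proportional to the multiexponential
#' \eqn{\sum_i A_i\,\mathrm{conv}(\tau_i)(t)}, scaled so the expected total
#' equals `total_counts`, then Poisson-sampled per bin. The Gaussian IRF is
#' also returned as a trace on the same axis (normalized to its maximum),
#' for reconvolution fitting against a measured-style IRF.
#'
#' @param lifetimes ps.
#' @param amplitudes relative emission amplitudes, >= 0, not all zero.
#' @param irf an [irf_model()].
#' @param delays ps (may be log-spaced, as in gate-scanned upconversion).
#' @param total_counts expected total counts over the trace.
#' @param seed integer seed for the Poisson draw.
#' @param poisson if `FALSE`, return the expected (noise-free) counts.
#' @return list of class `fluorescence_decay` with `delays`, `counts`,
#'   `expected`, `irf` (model), `irf_trace`, `acquisition`.
#' @export
simulate_fluorescence <- function(lifetimes, amplitudes, irf, delays,
                                  total_counts = 1e6, seed = 1L,
                                  poisson = TRUE) {
  tag_assert(all(amplitudes >= 0) && any(amplitudes > 0),
             "amplitudes must be >= 0 and not all zero")
  tag_assert(all(lifetimes > 0), "lifetimes must be positive")
  tag_assert(total_counts > 0, "total_counts must be positive")
  shape <- drop(conv_basis(delays, lifetimes, irf) %*% amplitudes)
  expected <- shape * (total_counts / sum(shape))
  counts <- if (poisson) {
    withr::with_seed(seed, stats::rpois(length(expected), expected))
  } else expected
  fluorescence_decay(delays, counts, irf = irf,
                     acquisition = "upconversion",
                     expected = expected)
}
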