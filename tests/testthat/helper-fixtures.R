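# Shared fixtures and independent oracles, built in code at test time.

# small rectangular matrix with known entries
tiny_matrix <- function() {
  spectral_time_matrix(
    wavelengths = c(400, 500),
    delays = c(-0.5, 0, 1),
    values = matrix(c(1, 2, 3, 4, 5, 6), nrow = 3),
    pump_nm = 410, label = "tiny")
}

# Independent numerical-convolution oracle for the Gaussian-IRF-convolved
# exponential: adaptive quadrature restricted to the Gaussian's support
# (an infinite-range integrate() misses the narrow peak).
conv_oracle <- function(t, tau, sigma, t0 = 0) {
  vapply(t, function(ti) {
    hi <- min(ti, t0 + 12 * sigma)
    lo <- t0 - 12 * sigma
    if (hi <= lo) return(0)
    stats::integrate(function(s) stats::dnorm(s, t0, sigma) *
                       exp(-(ti - s) / tau),
                     lo, hi, rel.tol = 1e-12, abs.tol = 1e-14)$value
  }, numeric(1))
}

fwhm_of <- function(sigma) sigma * 2 * sqrt(2 * log(2))

# small two-component synthetic for fast pipeline tests
small_two_comp <- function(lifetimes = c(0.4, 4.3), noise_frac = 0,
                           seed = 1, n_wavelengths = 12, t_max = 100) {
  wl <- seq(350, 750, length.out = n_wavelengths)
  s1 <- gaussian_band_spectrum(wl, list(c(410, 40, -5), c(470, 50, 3)))
  s2 <- gaussian_band_spectrum(wl, list(c(430, 45, 4), c(600, 80, -2)))
  comps <- list(list(lifetime = lifetimes[1], spectrum = s1),
                list(lifetime = lifetimes[2], spectrum = s2))
  noise <- if (noise_frac > 0) noise_frac * 5 else 0
  spec <- simulation_spec(comps, irf = irf_model(fwhm = 0.1),
                          noise_sd = noise, seed = seed)
  simulate_ta(spec, wavelengths = wl,
              delays = make_time_grid(20, 0.5, t_max, 10))
}
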