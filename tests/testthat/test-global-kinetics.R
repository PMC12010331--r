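test_that("closed-form IRF convolution matches the quadrature oracle to 1e-6", {
  t <- c(seq(-0.6, 2, by = 0.05), 5, 20, 80)
  for (sigma in c(0.02, 0.1, 0.3)) {
    for (tau in c(0.05, 0.4, 4.3, 100)) {
      got <- irf_convolved_exponential(t, tau, irf_model(0, fwhm_of(sigma)))
      expect_lt(max(abs(got - conv_oracle(t, tau, sigma))), 1e-6)
      expect_true(all(got >= 0 & got <= 1))
    }
  }
})

test_that("convolution limits: sharp IRF, pre-zero tail, slow lifetime", {
  sharp <- irf_model(0, fwhm_of(1e-6))
  expect_equal(irf_convolved_exponential(0.4, 0.4, sharp), exp(-1),
               tolerance = 1e-6)
  expect_lt(irf_convolved_exponential(-0.5, 0.4, irf_model(0, fwhm_of(0.05))),
            1e-12)
  expect_equal(irf_convolved_exponential(1, 1000, irf_model(0, 0.1)),
               exp(-0.001), tolerance = 1e-9)
})

test_that("SVD rank: exact rank-2, pure noise, and noisy two-component data", {
  delays <- make_time_grid(20, 0.5, 1000, 20)
  clean <- simulate_ta(fcc_like_spec(noise_frac = 0, seed = 5))
  r <- svd_rank(clean, rep(1e-3, length(clean$wavelengths)))
  expect_equal(r$n_components, 2)
  expect_lt(r$singular_values[3] / r$singular_values[1], 1e-10)

  zero_rank <- vapply(1:10, function(s) {
    v <- withr::with_seed(s, matrix(stats::rnorm(117 * 80, sd = 0.15),
                                    117, 80))
    mm <- spectral_time_matrix(seq(290, 1000, length.out = 80), delays, v)
    svd_rank(mm, rep(0.15, 80))$n_components
  }, numeric(1))
  expect_gte(sum(zero_rank == 0), 9)

  noisy_rank <- vapply(1:5, function(s) {
    sp <- fcc_like_spec(seed = s)
    svd_rank(simulate_ta(sp), rep(sp$noise_sd, 80))$n_components
  }, numeric(1))
  expect_true(all(noisy_rank == 2))
})

test_that("variable projection refits its own truth and prefers n = 2", {
  m <- small_two_comp(noise_frac = 0)
  noise <- rep(0.01, length(m$wavelengths))
  fit <- global_fit(m, 2, c(0.4, 4.3), irf_model(fwhm = 0.1), noise)
  expect_equal(fit$lifetimes, c(0.4, 4.3), tolerance = 1e-6)
  expect_lt(fit$chi2_reduced, 1e-10)

  m2 <- small_two_comp(noise_frac = 0.02, seed = 6)
  noise2 <- estimate_noise(m2, 0.1)
  fit2 <- global_fit(m2, 2, c(0.2, 8), irf_model(fwhm = 0.15), noise2)
  expect_true(all(abs(fit2$lifetimes - c(0.4, 4.3)) / c(0.4, 4.3) < 0.1))
  fit1 <- global_fit(m2, 1, 1, irf_model(fwhm = 0.15), noise2)
  expect_gt(fit1$chi2_reduced / fit2$chi2_reduced, 2)
})

test_that("fitted DADS reproduce the generator spectra (cosine >= 0.97)", {
  sp <- fcc_like_spec(seed = 8)
  m <- simulate_ta(sp)
  fit <- global_fit(m, 2, c(0.2, 8), irf_model(fwhm = 0.15),
                    estimate_noise(m, 0.1))
  for (k in 1:2) {
    truth <- sp$components[[k]]$spectrum$values
    got <- fit$dads$spectra[, k]
    cosine <- sum(truth * got) / sqrt(sum(truth^2) * sum(got^2))
    expect_gt(cosine, 0.97)
  }
})

test_that("sequential concentrations: initial conditions and peak time", {
  sharp <- irf_model(0, fwhm_of(1e-5))
  t <- seq(0, 20, by = 1e-3)
  p1 <- sequential_concentrations(0.4, sharp, t)
  expect_equal(p1$c[, 1], irf_convolved_exponential(t, 0.4, sharp))

  p2 <- sequential_concentrations(c(0.4, 4.3), sharp, t)
  # just after time zero the prepared state carries all population
  expect_equal(p2$c[2, 1], 1, tolerance = 1e-2)
  expect_lt(abs(p2$c[2, 2]), 1e-2)
  k1 <- 1 / 0.4; k2 <- 1 / 4.3
  t_peak_analytic <- log(k1 / k2) / (k1 - k2)  # 1.0474 ps
  expect_equal(t[which.max(p2$c[, 2])], t_peak_analytic, tolerance = 1e-2)
  expect_error(sequential_concentrations(c(1, 1), sharp, t),
               class = "tag_degenerate_rates_error")
})

test_that("species fractions sum to one and cross over as populations evolve", {
  irf <- irf_model(fwhm = 0.1)
  t <- make_time_grid(20, 0.5, 100, 10)
  p <- sequential_concentrations(c(0.4, 4.3), irf, t)
  f <- species_fractions(p)
  expect_true(all(abs(rowSums(f$fractions) - 1) < 1e-12))
  # early delays: species 1 dominates; after the crossing, species 2
  expect_gt(f$fractions[which.min(abs(f$delays - 0.1)), 1], 0.5)
  expect_gt(f$fractions[which.min(abs(f$delays - 3)), 2], 0.5)
  p1 <- sequential_concentrations(2, irf, t)
  expect_true(all(species_fractions(p1)$fractions == 1))
})

test_that("EADS obey the sum rule and reconstruct the same surface as DADS", {
  wl <- seq(350, 750, length.out = 12)
  d1 <- gaussian_band_spectrum(wl, list(c(410, 40, -5)))$values
  d2 <- gaussian_band_spectrum(wl, list(c(500, 60, 3)))$values
  d3 <- gaussian_band_spectrum(wl, list(c(650, 70, -1)))$values
  for (n in 1:3) {
    taus <- c(0.4, 4.3, 40)[seq_len(n)]
    dads <- component_spectra("DADS", taus, wl,
                              cbind(d1, d2, d3)[, seq_len(n), drop = FALSE])
    eads <- dads_to_eads(dads)
    expect_equal(eads$spectra[, 1], rowSums(dads$spectra))  # exact sum rule
    irf <- irf_model(fwhm = 0.1)
    t <- make_time_grid(20, 0.5, 100, 10)
    conv <- vapply(taus, function(tt) irf_convolved_exponential(t, tt, irf),
                   numeric(length(t)))
    prof <- sequential_concentrations(taus, irf, t)
    surf_dads <- conv %*% t(dads$spectra)
    surf_eads <- prof$c %*% t(eads$spectra)
    expect_lt(max(abs(surf_dads - surf_eads)), 1e-9 * max(abs(surf_dads)))
  }
  dads2 <- component_spectra("DADS", c(1, 1 + 1e-9), wl, cbind(d1, d2))
  expect_error(dads_to_eads(dads2), class = "tag_degenerate_rates_error")
})
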