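test_that("time grid: linear window point count and log-point enumeration", {
  g <- make_time_grid(20, 0.5, 0.5, 10)       # linear part only
  expect_equal(length(g), 2 * 0.5 / 0.02 + 1) # 51 points
  expect_equal(g[1], -0.5)
  expect_equal(g[length(g)], 0.5)

  # independent enumeration of the log tail: edge * 10^(j/ppd) <= t_max
  g2 <- make_time_grid(20, 0.5, 500, 10)
  expected_log <- 0.5 * 10^(seq_len(100) / 10)
  expected_log <- expected_log[expected_log <= 500 * (1 + 1e-12)]
  expect_equal(length(expected_log), 30)
  expect_equal(g2[g2 > 0.5 + 1e-12], expected_log)
  expect_true(all(diff(g2) > 0))
  expect_error(make_time_grid(-20, 0.5, 10, 10), class = "tag_parameter_error")
})

test_that("gaussian band spectra evaluate amplitudes at centers and add", {
  wl <- seq(300, 800, by = 2)
  s <- gaussian_band_spectrum(wl, list(c(410, 30, -1)))
  expect_equal(s$values[wl == 410], -1)
  expect_equal(which.min(s$values), which(wl == 410))
  s2 <- gaussian_band_spectrum(wl, list(c(410, 30, -1), c(410, 30, -1)))
  expect_equal(s2$values, 2 * s$values)
  expect_error(gaussian_band_spectrum(wl, list(c(410, -5, 1))),
               class = "tag_parameter_error")
})

test_that("simulated matrices decay fully, are seed-deterministic and linear", {
  wl <- seq(350, 750, length.out = 8)
  s1 <- gaussian_band_spectrum(wl, list(c(450, 60, 4)))
  comp <- list(list(lifetime = 0.5, spectrum = s1))
  spec <- simulation_spec(comp, irf = irf_model(fwhm = 0.1), seed = 7)
  delays <- make_time_grid(20, 0.5, 100, 10)
  m <- simulate_ta(spec, wl, delays)
  # decayed by >= 100 tau
  expect_lt(max(abs(m$values[delays > 50, ])), 1e-6 * max(abs(m$values)))

  spec_n <- simulation_spec(comp, irf = irf_model(fwhm = 0.1),
                            noise_sd = 0.2, seed = 7)
  expect_identical(simulate_ta(spec_n, wl, delays)$values,
                   simulate_ta(spec_n, wl, delays)$values)

  # linearity in the component set (noise off)
  s2 <- gaussian_band_spectrum(wl, list(c(600, 80, -2)))
  comp2 <- list(list(lifetime = 5, spectrum = s2))
  m1 <- simulate_ta(simulation_spec(comp, irf = irf_model(fwhm = 0.1)),
                    wl, delays)
  m2 <- simulate_ta(simulation_spec(comp2, irf = irf_model(fwhm = 0.1)),
                    wl, delays)
  m12 <- simulate_ta(simulation_spec(c(comp, comp2),
                                     irf = irf_model(fwhm = 0.1)),
                     wl, delays)
  expect_equal(m12$values, m1$values + m2$values, tolerance = 1e-12)
})

test_that("sharp-IRF simulation hits S * exp(-1) at t = tau", {
  wl <- c(400, 500)
  s <- spectrum(wl, c(3, -2))
  spec <- simulation_spec(list(list(lifetime = 0.7, spectrum = s)),
                          irf = irf_model(fwhm = fwhm_of(1e-4)))
  m <- simulate_ta(spec, wl, delays = c(-1, 0.7))
  expect_equal(m$values[2, ], s$values * exp(-1), tolerance = 1e-4)
})

test_that("coherent artifact tracks the chirp curve in time", {
  wl <- seq(300, 900, length.out = 15)
  s <- gaussian_band_spectrum(wl, list(c(500, 80, 1)))
  delays <- seq(-0.5, 0.5, by = 0.02)
  for (chirp in list(0, c(-0.08, 0.2))) {
    spec <- simulation_spec(list(list(lifetime = 50, spectrum = s)),
                            irf = irf_model(fwhm = 0.1),
                            chirp_poly = chirp, artifact_amp = 30,
                            artifact_width = 0.03)
    m <- simulate_ta(spec, wl, delays)
    t_peak <- delays[apply(m$values, 2, which.max)]
    t0 <- taglobal:::chirp_t0(chirp, wl)
    expect_true(all(abs(t_peak - t0) <= 0.02 + 1e-9))
  }
})

test_that("fluorescence expected counts normalize, are deterministic, obey e^-1", {
  delays <- make_time_grid(100, 1, 900, 15)
  irf <- irf_model(fwhm = 0.15)
  d <- simulate_fluorescence(c(0.6), 1, irf, delays, 5e5, seed = 4)
  expect_equal(sum(d$expected), 5e5, tolerance = 1e-9)
  d2 <- simulate_fluorescence(c(0.6), 1, irf, delays, 5e5, seed = 4)
  expect_identical(d$counts, d2$counts)

  # sharp IRF: expected counts at t = t0 + tau are e^-1 of the peak of the
  # decay (just past time zero)
  dn <- simulate_fluorescence(c(2), 1, irf_model(fwhm = fwhm_of(1e-4)),
                              c(0.01, 2.01), 1e4, poisson = FALSE)
  expect_equal(dn$expected[2] / dn$expected[1], exp(-1), tolerance = 1e-4)
  expect_error(simulate_fluorescence(c(1), 0, irf, delays, 1e4),
               class = "tag_parameter_error")
})

test_that("fluorescence counts are Poisson: variance matches mean per bin", {
  irf <- irf_model(fwhm = 0.15)
  delays <- c(0.2, 0.5, 1)
  draws <- vapply(1:1000, function(s)
    simulate_fluorescence(c(0.6), 1, irf, delays, 3000, seed = s)$counts[2],
    numeric(1))
  mu <- simulate_fluorescence(c(0.6), 1, irf, delays, 3000,
                              poisson = FALSE)$expected[2]
  # chi-square test of the variance at the 1% level
  stat <- (length(draws) - 1) * stats::var(draws) / mu
  expect_gt(stat, stats::qchisq(0.005, length(draws) - 1))
  expect_lt(stat, stats::qchisq(0.995, length(draws) - 1))
})

test_that("sequential simulation rejects duplicate lifetimes", {
  wl <- c(400, 500)
  s <- spectrum(wl, c(1, 1))
  spec <- simulation_spec(list(list(lifetime = 1, spectrum = s),
                               list(lifetime = 1, spectrum = s)),
                          model = "sequential")
  expect_error(simulate_ta(spec, wl, c(0, 1)),
               class = "tag_degenerate_rates_error")
})
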