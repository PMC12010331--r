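test_that("lifetime grid point counts follow the rounding rule", {
  expect_equal(as.numeric(build_lifetime_grid(1, 10, 1)), c(1, 10))
  expect_equal(as.numeric(build_lifetime_grid(1, 100, 1)), c(1, 10, 100))
  # analysis defaults: round(20 * log10(1000 / 0.02)) + 1 = 95 points
  g <- build_lifetime_grid(0.02, 1000, 20)
  expect_length(g, 95)
  expect_equal(g[1], 0.02)
  expect_equal(g[95], 1000)
  # log-uniform spacing
  expect_lt(diff(range(diff(log(as.numeric(g))))), 1e-9)
  expect_error(build_lifetime_grid(10, 1, 20), class = "tag_parameter_error")
})

test_that("design matrix columns are bounded convolved exponentials", {
  grid <- build_lifetime_grid(0.02, 1000, 20)
  t <- make_time_grid(20, 0.5, 1000, 20)
  M <- lda_design_matrix(t, grid, irf_model(fwhm = 0.1))
  expect_true(all(M >= -1e-9 & M <= 1 + 1e-9))
  # sharp-IRF limit: entry e^-1 at t = tau
  Ms <- lda_design_matrix(c(1), build_lifetime_grid(1, 10, 1),
                          irf_model(0, fwhm_of(1e-6)))
  expect_equal(Ms[1, 1], exp(-1), tolerance = 1e-6)
  expect_equal(
    lda_design_matrix(1, build_lifetime_grid(1000, 2000, 1),
                      irf_model(fwhm = 0.1))[1, 1],
    exp(-0.001), tolerance = 1e-9)
})

test_that("maximum entropy: zero data give zero amplitudes; huge alpha kills them", {
  grid <- build_lifetime_grid(0.05, 100, 10)
  t <- make_time_grid(20, 0.5, 100, 10)
  zeros <- spectral_time_matrix(c(400, 500), t,
                                matrix(0, length(t), 2))
  map0 <- maxent_fit(zeros, grid, irf_model(fwhm = 0.1),
                     noise = c(0.1, 0.1), alpha = 1)
  expect_true(all(map0$amplitudes == 0))

  m <- small_two_comp(noise_frac = 0)
  noise <- rep(0.05, length(m$wavelengths))
  map_inf <- maxent_fit(m, grid, irf_model(fwhm = 0.1), noise, alpha = 1e12)
  expect_lt(max(abs(map_inf$amplitudes)), 1e-3)
  expect_equal(map_inf$chi2, sum(sweep(m$values, 2, noise, "/")^2),
               tolerance = 1e-3)
})

test_that("noiseless single-exponential mass centers on the true lifetime
           and the fitted signal matches a ridge oracle", {
  grid <- build_lifetime_grid(0.02, 1000, 20)
  tau <- as.numeric(grid)
  tau_true <- tau[which.min(abs(tau - 1))]     # an exact grid point
  t <- make_time_grid(20, 0.5, 1000, 20)
  irf <- irf_model(fwhm = 0.1)
  y <- 5 * irf_convolved_exponential(t, tau_true, irf)
  m <- spectral_time_matrix(c(400, 500), t, cbind(y, y))
  map <- maxent_fit(m, grid, irf, noise = c(0.01, 0.01), alpha = 0.01)
  a <- map$amplitudes[1, ]
  centroid <- exp(sum(abs(a) * log(tau)) / sum(abs(a)))
  step <- tau[2] / tau[1]
  expect_lt(abs(log(centroid / tau_true)), log(step))
  expect_equal(sum(a), 5, tolerance = 0.05)   # total amplitude conserved

  # fitted-signal equivalence with a quadratic-ridge direct solve of
  # matched curvature (entropy ~ a^2 / (4 m) near zero)
  M <- lda_design_matrix(t, grid, irf)
  mprior <- 0.01 * 5
  A_ridge <- solve(2 * crossprod(M) / 0.01^2 +
                     diag(0.01 / (2 * mprior), ncol(M)),
                   2 * crossprod(M, y) / 0.01^2)
  rel_rms <- sqrt(mean((M %*% A_ridge - M %*% a)^2)) / sqrt(mean(y^2))
  expect_lt(rel_rms, 0.01)
})

test_that("misfit rises and entropy falls monotonically along the alpha scan", {
  m <- small_two_comp(noise_frac = 0.02, seed = 12)
  grid <- build_lifetime_grid(0.05, 100, 10)
  noise <- estimate_noise(m, 0.1)
  sel <- l_curve_select(m, grid, irf_model(fwhm = 0.1), noise,
                        alphas = 10^seq(-2, 3, length.out = 9))
  expect_true(all(diff(sel$table$chi2) >= -1e-6 * sel$table$chi2[-1]))
  expect_true(all(diff(sel$table$entropy) <= 1e-6 * sel$table$entropy[-1]))
  # selected alpha strictly inside the scanned range
  expect_gt(sel$alpha_opt, min(sel$table$alpha))
  expect_lt(sel$alpha_opt, max(sel$table$alpha))
  expect_equal(sel$map$alpha, sel$alpha_opt)
})

test_that("dynamical content is the wavelength quadrature of the map", {
  grid <- build_lifetime_grid(0.1, 10, 2)
  map <- structure(list(grid = grid, wavelengths = c(400, 500),
                        amplitudes = rbind(c(3, 0, 0, 0, 0),
                                           c(4, 0, 0, 0, 0)),
                        alpha = 1, chi2 = 0, entropy = 0),
                   class = "lifetime_density_map")
  D <- dynamical_content(map)
  expect_equal(D$d[1], 5)                  # 3-4-5 over two wavelengths
  expect_equal(D$d[-1], rep(0, 4))
  map2 <- map; map2$amplitudes <- -2 * map$amplitudes
  expect_equal(dynamical_content(map2)$d, 2 * D$d)  # |c|-homogeneous
  map3 <- map; map3$amplitudes <- map$amplitudes[2:1, ]
  expect_equal(dynamical_content(map3)$d, D$d)      # permutation-invariant
})

test_that("component windows respect the artifact floor and split equal peaks", {
  grid <- build_lifetime_grid(0.01, 100, 10)
  tau <- as.numeric(grid)
  # peaks at 0.05 ps (sub-floor) and 4 ps
  d <- exp(-(log(tau / 0.05))^2) + exp(-(log(tau / 4))^2)
  D <- structure(list(grid = grid, d = d), class = "dynamical_content")
  w <- find_components(D, floor_ps = 0.15)
  expect_length(w, 1)
  expect_equal(w[[1]]$peak_lifetime, 4, tolerance = 0.12)
  expect_error(find_components(
    structure(list(grid = grid, d = exp(-(log(tau / 0.05))^2)),
              class = "dynamical_content"), floor_ps = 0.15),
    class = "tag_no_component_error")

  # two equal peaks whose half-max regions overlap share a boundary at the
  # log-midpoint of the peaks (the valley midpoint)
  d2 <- 0.6 + 0.4 * exp(-(log(tau / 0.5) / 0.5)^2) +
    0.4 * exp(-(log(tau / 8) / 0.5)^2)
  D2 <- structure(list(grid = grid, d = d2), class = "dynamical_content")
  w2 <- find_components(D2, floor_ps = 0.15)
  expect_length(w2, 2)
  expect_equal(w2[[1]]$hi, w2[[2]]$lo, tolerance = 1e-9)
  expect_equal(w2[[1]]$hi, sqrt(w2[[1]]$grid_lifetime * w2[[2]]$grid_lifetime),
               tolerance = 1e-9)
})

test_that("DADS extraction sums map windows and is partition-additive", {
  grid <- build_lifetime_grid(0.1, 100, 5)
  tau <- as.numeric(grid)
  set.seed(42)
  amps <- matrix(stats::rnorm(3 * length(tau)), nrow = 3)
  map <- structure(list(grid = grid, wavelengths = c(400, 500, 600),
                        amplitudes = amps, alpha = 1, chi2 = 0, entropy = 0),
                   class = "lifetime_density_map")
  whole <- extract_dads(map, list(list(peak_lifetime = 1, lo = 0.05,
                                       hi = 200)))
  expect_equal(whole$spectra[, 1], rowSums(amps))
  cut <- sqrt(tau[8] * tau[9])
  parts <- extract_dads(map, list(
    list(peak_lifetime = 0.5, lo = 0.05, hi = cut),
    list(peak_lifetime = 10, lo = cut, hi = 200)))
  expect_equal(rowSums(parts$spectra), whole$spectra[, 1])
  expect_error(extract_dads(map, list(list(peak_lifetime = 1, lo = 0.11,
                                           hi = 0.12))),
               class = "tag_empty_window_error")
})
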