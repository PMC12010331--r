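# Global kinetic analysis: Gaussian-IRF-convolved exponentials in closed
# form, SVD component-count selection, variable-projection multiexponential
# fitting, sequential-model concentration profiles and the DADS -> EADS
# conversion.

# Scaled complementary error function erfcx(x) = exp(x^2) erfc(x), stable
# for large positive x (computed through the normal log-tail so exp(x^2)
# never overflows).
erfcx_pos <- function(x) {
  exp(x^2 + stats::pnorm(sqrt(2) * x, lower.tail = FALSE, log.p = TRUE) +
        log(2))
}

#' Gaussian-IRF-convolved exponential decay
#'
#' Closed form of the convolution of a normalized exponential decay
#' \eqn{e^{-t/\tau}} (unit step at t = 0) with a Gaussian instrument
#' response of standard deviation \eqn{\sigma} centered at \eqn{t_0}:
#' \deqn{c(t) = \tfrac12 \exp\!\left(\frac{\sigma^2}{2\tau^2} -
#'   \frac{t - t_0}{\tau}\right)\left[1 + \mathrm{erf}\!\left(
#'   \frac{t - t_0 - \sigma^2/\tau}{\sigma\sqrt2}\right)\right].}
#' The implementation switches to a scaled-erfc form when the exponent is
#' large, so the value is finite and accurate for all argument
#' combinations; the result lies in `[0, 1]`.
#'
#' @param t delays, ps.
#' @param tau lifetime, ps (> 0).
#' @param irf an [irf_model()].
#' @return numeric vector of the same length as `t`.
#' @export
irf_convolved_exponential <- function(t, tau, irf) {
  tag_assert(tau > 0, "tau must be positive")
  s <- irf$sigma
  x <- t - irf$t0
  # z > 0 branch: c = 0.5 * erfcx(z) * exp(-x^2 / (2 s^2)), z = (s/tau - x/s)/sqrt(2)
  z <- (s / tau - x / s) / sqrt(2)
  out <- numeric(length(x))
  pos <- z > 0
  if (any(pos))
    out[pos] <- 0.5 * erfcx_pos(z[pos]) * exp(-x[pos]^2 / (2 * s^2))
  if (any(!pos)) {
    # z <= 0 means x >= s^2/tau, so the exponent is <= -s^2/(2 tau^2) < 0:
    # the direct form cannot overflow here
    out[!pos] <- 0.5 * exp(s^2 / (2 * tau^2) - x[!pos] / tau) *
      2 * stats::pnorm(sqrt(2) * z[!pos], lower.tail = FALSE)
  }
  pmin(pmax(out, 0), 1)
}

# Marchenko-Pastur median eigenvalue of X'X/Q for an q x Q (q <= Q) unit
# Gaussian matrix, ratio gamma = q/Q. Solved numerically from the density.
mp_median <- function(gamma) {
  a <- (1 - sqrt(gamma))^2
  b <- (1 + sqrt(gamma))^2
  dens <- function(x) sqrt(pmax((b - x) * (x - a), 0)) / (2 * pi * gamma * x)
  cdf <- function(q) stats::integrate(dens, a, q, rel.tol = 1e-8)$value
  stats::uniroot(function(q) cdf(q) - 0.5, c(a + 1e-12 * (b - a), b),
                 tol = 1e-10)$root
}

#' Number of kinetic components by singular value decomposition
#'
#' Whitens the matrix by the per-wavelength noise (each wavelength column
#' divided by its sigma), takes the SVD and counts singular values above a
#' random-matrix threshold: the optimal hard threshold of Gavish and
#' Donoho, \eqn{\lambda^*(\beta)\sqrt{Q}\,\hat\sigma} with
#' \eqn{\beta = q/Q} the aspect ratio, which sits safely above the
#' Marchenko-Pastur bulk edge \eqn{\hat\sigma(\sqrt{n_t}+\sqrt{n_\lambda})}
#' and so is robust to edge fluctuations and to the sampling error of the
#' per-wavelength noise estimates. The unit noise \eqn{\hat\sigma} is
#' estimated from the median singular value against the Marchenko-Pastur
#' median. A relative floor of `1e-8` of the leading singular value guards
#' the noiseless case.
#'
#' @param matrix a [spectral_time_matrix()].
#' @param noise per-wavelength noise sd vector, mOD (see [estimate_noise()]).
#' @return list with `n_components`, the `singular_values` of the whitened
#'   matrix and the `threshold` (for audit).
#' @export
svd_rank <- function(matrix, noise) {
  stopifnot(inherits(matrix, "spectral_time_matrix"))
  tag_assert(length(noise) == length(matrix$wavelengths) && all(noise > 0),
             "noise must be one positive sd per wavelength")
  x <- sweep(matrix$values, 2, noise, "/")
  s <- svd(x, nu = 0, nv = 0)$d
  n <- nrow(x); p <- ncol(x)
  q <- min(n, p); Q <- max(n, p)
  beta <- q / Q
  sigma_unit <- stats::median(s) / sqrt(Q * mp_median(beta))
  lambda_star <- sqrt(2 * (beta + 1) +
                        8 * beta / (beta + 1 + sqrt(beta^2 + 14 * beta + 1)))
  thr <- max(sigma_unit * lambda_star * sqrt(Q), s[1] * 1e-8)
  list(n_components = sum(s > thr), singular_values = s, threshold = thr)
}

# Coefficients b[j, l] of the sequential irreversible scheme 1 -> 2 -> ... -> n:
# c_l(t) = sum_j b[j, l] conv(k_j)(t), with k = 1/tau. Upper triangular.
sequential_coefficients <- function(lifetimes) {
  tag_assert(all(lifetimes > 0), "lifetimes must be positive")
  k <- 1 / lifetimes
  n <- length(k)
  if (n > 1) {
    gaps <- abs(outer(k, k, "-")) / outer(k, k, pmax)
    diag(gaps) <- Inf
    if (min(gaps) <= 1e-6)
      tag_stop("duplicate rates: sequential-model coefficients are singular",
               "tag_degenerate_rates_error")
  }
  b <- matrix(0, n, n)
  for (l in seq_len(n)) {
    pref <- if (l == 1) 1 else prod(k[seq_len(l - 1)])
    for (j in seq_len(l)) {
      denom <- prod(k[setdiff(seq_len(l), j)] - k[j])
      b[j, l] <- pref / ifelse(l == 1, 1, denom)
    }
  }
  b
}

#' Sequential-model concentration profiles
#'
#' Concentrations \eqn{c_l(t)} of the irreversible sequential scheme
#' 1 -> 2 -> ... -> n with rates \eqn{k_l = 1/\tau_l}, each stage convolved
#' with the Gaussian IRF. The first species is the plain convolved
#' exponential; later species are the analytic sums
#' \eqn{c_l = \sum_{j \le l} b_{jl}\, \mathrm{conv}(k_j)} with the standard
#' Bateman coefficients. Duplicate rates are an error (the coefficients are
#' singular); perturb the lifetimes instead.
#'
#' @param lifetimes ps, pairwise distinct (relative gap > 1e-6).
#' @param irf an [irf_model()].
#' @param delays ps.
#' @return list with `delays` and matrix `c` `[delay, component]`.
#' @export
sequential_concentrations <- function(lifetimes, irf, delays) {
  b <- sequential_coefficients(lifetimes)
  basis <- vapply(lifetimes, function(tau)
    irf_convolved_exponential(delays, tau, irf), numeric(length(delays)))
  conc <- basis %*% b
  list(delays = delays, c = conc, lifetimes = lifetimes)
}

#' Species fractions along the delay axis
#'
#' Normalizes sequential-model concentrations to fractions
#' \eqn{f_l(t) = c_l(t) / \sum_m c_m(t)}. Delays where the total
#' concentration is below 1e-12 (before excitation, or after complete
#' decay) are dropped and reported.
#'
#' @param profiles output of [sequential_concentrations()].
#' @return list with `delays`, `fractions` (rows sum to 1) and
#'   `dropped_delays`.
#' @export
species_fractions <- function(profiles) {
  tot <- rowSums(profiles$c)
  keep <- tot >= 1e-12
  f <- profiles$c[keep, , drop = FALSE] / tot[keep]
  list(delays = profiles$delays[keep], fractions = f,
       dropped_delays = profiles$delays[!keep])
}

#' Convert DADS to EADS under a sequential scheme
#'
#' Both representations describe the same fitted surface: parallel
#' decay-associated spectra satisfy
#' \eqn{\sum_k \mathrm{DADS}_k\,\mathrm{conv}(k_k) =
#'  \sum_l \mathrm{EADS}_l\, c_l}. Expanding the sequential concentrations
#' in the convolved-exponential basis gives the exact triangular relation
#' `DADS = EADS %*% t(B)`; this function inverts it. The first EADS always
#' equals the sum of all DADS (the initially prepared state carries all
#' subsequent evolution).
#'
#' @param dads a [component_spectra()] of kind `"DADS"`.
#' @param lifetimes optional lifetimes overriding the tags in `dads`.
#' @return A [component_spectra()] of kind `"EADS"`.
#' @export
dads_to_eads <- function(dads, lifetimes = dads$lifetimes) {
  stopifnot(inherits(dads, "component_spectra"))
  tag_assert(dads$kind == "DADS", "input must be of kind DADS")
  b <- sequential_coefficients(lifetimes)
  # DADS_j = sum_l b[j, l] EADS_l  =>  EADS = DADS %*% t(solve(b))
  eads <- t(solve(b, t(dads$spectra)))
  component_spectra("EADS", lifetimes, dads$wavelengths, eads)
}

# Basis of IRF-convolved exponentials, [delay, lifetime].
conv_basis <- function(delays, lifetimes, irf) {
  matrix(vapply(lifetimes, function(tau)
    irf_convolved_exponential(delays, tau, irf), numeric(length(delays))),
    nrow = length(delays))
}

#' Global kinetic analysis by variable projection
#'
#' Fits the full matrix with `n` IRF-convolved exponential components plus
#' a fitted Gaussian IRF (center and width). For each trial of the
#' nonlinear parameters (log-lifetimes, t0, log-fwhm) the component spectra
#' (DADS) are solved per wavelength by linear least squares against the
#' convolved-exponential basis; the nonlinear parameters are optimized on
#' the projected, noise-weighted residual (Levenberg-Marquardt). Lifetimes
#' are log-parameterized and bounded to `[1e-3, 1e4]` ps.
#'
#' If two fitted lifetimes collapse (adjacent ratio < 1.05) the model is
#' refit with `n - 1` components, with a warning.
#'
#' @param matrix a [spectral_time_matrix()].
#' @param n number of exponential components (>= 1).
#' @param init_lifetimes initial lifetimes, ps, length `n`, distinct.
#' @param init_irf an [irf_model()] initial guess.
#' @param noise per-wavelength noise sd vector, mOD.
#' @param fit_irf logical; fit t0 and fwhm (default) or hold them fixed.
#' @return list of class `kinetic_fit` with `lifetimes` (ascending), `irf`,
#'   `dads` (a [component_spectra()]), `chi2_reduced`, `residuals` matrix,
#'   `covariance` of the nonlinear parameters and `convergence` info.
#' @export
global_fit <- function(matrix, n, init_lifetimes, init_irf, noise,
                       fit_irf = TRUE) {
  stopifnot(inherits(matrix, "spectral_time_matrix"),
            inherits(init_irf, "irf_model"))
  tag_assert(n >= 1 && length(init_lifetimes) == n,
             "need n positive initial lifetimes")
  tag_assert(all(init_lifetimes > 0), "initial lifetimes must be positive")
  tag_assert(length(noise) == length(matrix$wavelengths) && all(noise > 0),
             "noise must be one positive sd per wavelength")
  t <- matrix$delays
  y <- matrix$values
  w <- rep(1 / noise, each = length(t))  # weights, column-major like y

  project <- function(par) {
    taus <- exp(par[seq_len(n)])
    irf <- irf_model(t0 = if (fit_irf) par[n + 1] else init_irf$t0,
                     fwhm = if (fit_irf) exp(par[n + 2]) else init_irf$fwhm)
    basis <- conv_basis(t, taus, irf)
    amps <- qr.solve(basis, y)               # [component, wavelength]
    fitted <- basis %*% amps
    list(res = as.vector(y - fitted) * w, amps = amps, irf = irf,
         taus = taus, fitted = fitted)
  }
  par0 <- c(log(init_lifetimes),
            if (fit_irf) c(init_irf$t0, log(init_irf$fwhm)))
  lower <- c(rep(log(1e-3), n), if (fit_irf) c(-Inf, log(1e-4)))
  upper <- c(rep(log(1e4), n), if (fit_irf) c(Inf, log(10)))
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(p) project(p)$res,
    control = minpack.lm::nls.lm.control(
      maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  if (fit$info == 0)
    tag_stop(sprintf("global fit did not converge: %s", fit$message),
             "tag_convergence_error")
  sol <- project(fit$par)
  taus <- sort(sol$taus)
  if (n > 1 && any(taus[-1] / taus[-n] < 1.05)) {
    warning("lifetime collapse (adjacent ratio < 1.05); refitting with n - 1",
            call. = FALSE)
    keep <- c(TRUE, taus[-1] / taus[-n] >= 1.05)
    return(global_fit(matrix, n - 1, taus[keep][seq_len(n - 1)],
                      sol$irf, noise, fit_irf = fit_irf))
  }
  ord <- order(sol$taus)
  amps <- sol$amps[ord, , drop = FALSE]
  dof <- length(y) - (n * ncol(y) + length(par0))
  chi2 <- sum(sol$res^2)
  covar <- tryCatch(chi2 / dof * solve(fit$hessian),
                    error = function(e) matrix(NA_real_, length(par0),
                                               length(par0)))
  structure(list(
    lifetimes = sol$taus[ord], irf = sol$irf,
    dads = component_spectra("DADS", sol$taus[ord], matrix$wavelengths,
                             t(amps)),
    chi2_reduced = chi2 / dof,
    residuals = matrix(as.vector(y - sol$fitted), nrow(y), ncol(y)),
    covariance = covar, n_iter = fit$niter, info = fit$info,
    below_floor = sol$taus[ord] < 0.15), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit>\n  lifetimes (ps):",
      paste(signif(x$lifetimes, 4), collapse = ", "), "\n")
  if (any(x$below_floor))
    cat("  note: components < 0.15 ps lie within the IRF time scale\n")
  cat(sprintf("  IRF: t0 = %.4g ps, fwhm = %.4g ps\n", x$irf$t0, x$irf$fwhm))
  cat(sprintf("  reduced chi2: %.4g\n", x$chi2_reduced))
  invisible(x)
}
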