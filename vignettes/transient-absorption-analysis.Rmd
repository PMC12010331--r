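---
title: "Methods: lifetime distributions, global kinetics, and reconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime distributions, global kinetics, and reconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `taglobal`, the
assumptions they rest on, the numerical choices that matter, and where
the design was genuinely open, why it was resolved the way it was.

# The measurement model

A pump–probe experiment records differential absorbance
$\Delta A(\lambda, t)$ (mOD) on a wavelength axis (nm) and a delay axis
(ps). Internally, $t = 0$ is always the center of the instrument
response function (IRF) and negative delays are the pre-excitation
baseline. The IRF is modelled as a Gaussian of FWHM given by the
pump–probe cross-correlation (default 0.10 ps; fluorescence upconversion
0.15 ps), so an exponential decay with lifetime $\tau$ appears as the
closed form

$$ c(t) = \tfrac12\, e^{\sigma^2/2\tau^2 - t/\tau}
   \left[1 + \operatorname{erf}\!\left(\frac{t - \sigma^2/\tau}
   {\sigma\sqrt2}\right)\right], \qquad
   \sigma = \mathrm{fwhm}/(2\sqrt{2\ln 2}). $$

`irf_convolved_exponential()` evaluates this with a scaled-erfc rewrite
(via the normal log-tail) so it neither overflows nor loses precision
for any $(\sigma, \tau, t)$ combination; the unit tests pin it against
an adaptive-quadrature convolution oracle to better than $10^{-6}$.

Assumptions: the IRF is Gaussian and wavelength-independent *after*
chirp correction; kinetics are linear combinations of first-order
processes; noise is additive and uncorrelated between detector pixels
and delays (fluorescence counts instead carry Poisson statistics).

# Lifetime distribution analysis (LDA)

Each wavelength is expanded on a fixed log-uniform lifetime grid
(default $2\times 10^{-2}$–$10^3$ ps, 20 points/decade, 95 points — the
lower bound mirrors a typical first experimental delay). With design
matrix $M_{tj} = c_{\tau_j}(t)$ the signed amplitudes minimize

$$ Q(a) = \sum_t \left(\frac{y_t - (Ma)_t}{\sigma_\lambda}\right)^2
   + \alpha \sum_j \left[ a_j \operatorname{asinh}\frac{a_j}{2m}
   - \sqrt{a_j^2 + 4m^2} + 2m \right]. $$

The penalty is a signed-amplitude entropy: smooth, nonnegative, zero
only at $a = 0$, quadratic ($a^2/4m$) below the prior scale $m$ and
$|a|\log|a|$-like above it. $m$ defaults to 1% of the per-wavelength
peak $|\Delta A|$ (floored at $10^{-6}$ mOD): amplitudes below 1% of the
local signal are treated as "noise scale" and shrunk quadratically.

**Why the basis is IRF-convolved.** The grid's shortest lifetimes (0.02
ps) lie far below the IRF width; unconvolved exponentials there would
fit pure instrument response and turn the short-lifetime edge of the map
into an artifact.

**Solver.** $Q$ is smooth and strictly convex (the entropy Hessian
$1/\sqrt{a^2+4m^2}$ is positive everywhere), so each wavelength is
solved by damped Newton with Armijo backtracking, sharing $M^\top M$
across wavelengths. Quasi-Newton gradient methods were measured to stall
at weak regularization, where the sub-IRF basis columns are nearly
collinear; exact Newton converges in tens of iterations at every
$\alpha$. Convergence: relative $Q$ change below $10^{-10}$ or gradient
$\infty$-norm below $10^{-8}\max(1, Q)$; cap 200 iterations per
wavelength.

**Choosing $\alpha$.** `l_curve_select()` fits a ladder of 25
quarter-decade-spaced $\alpha$ values (warm-started strongest-first),
bracketing the point where $\chi^2$ equals the number of data points,
and returns the full l-curve table $(\alpha, \chi^2, R)$ with its
discrete curvature for audit. The *selection*, however, uses generalized
cross-validation,
$\mathrm{GCV}(\alpha) = (\chi^2/N)\,/\,(1 - \mathrm{df}(\alpha)/N)^2$,
with the effective degrees of freedom
$\mathrm{df} = \sum_\lambda \operatorname{tr}(H^{-1} G)$ computed from
each converged fit's local Hessian. This was a deliberate design
decision: on spectrally sparse data the log-entropy axis of the l-curve
spans an order of magnitude more than the log-misfit axis, the
max-curvature corner is then dominated by the penalty axis and lands at
over-smoothed $\alpha$ where adjacent lifetime peaks merge. GCV balances
misfit against flexibility directly and selects consistently across
noise realizations. If the GCV optimum falls on a scan boundary the
ladder extends itself (up to 24 extra points) so the reported optimum is
interior. The df trace is computed as
$n_\tau - \operatorname{tr}(H^{-1}D)$ so that the Cholesky jitter
occasionally needed near-singular $H$ biases df conservatively upward.

**Dynamical content and components.** $D(\tau_j) =
\sqrt{\sum_\lambda a(\lambda,\tau_j)^2}$. Local maxima with prominence
$\ge$ 5% of $\max D$ and lifetime above the 0.15 ps floor (events at or
below it are attributed to the coherent artifact and cross-phase
modulation) become components. Peak centers are refined below the grid
spacing by three-point parabolic interpolation of $\log D$ vs
$\log\tau$ — "the peak center" is an estimator choice, and sub-grid
refinement removes discretization error at no cost. Each component's
window is the contiguous region with $D$ above half the peak, expanded
half a grid step, clipped at log-midpoints between neighbouring peaks
and at the floor; DADS are the row sums of the map over the window.

**What LDA can and cannot deliver.** The entropy functional spreads
amplitude over neighbouring (nearly collinear) grid lifetimes by
construction; on the package's standard synthetic conditions the peak
*centers* scatter at the level of one grid step ($\approx$ 12%) between
noise realizations, with occasional two-step excursions. The parametric
global fit below recovers the same lifetimes roughly an order of
magnitude more precisely. This mirrors the intended division of labour:
LDA is the model-free survey; GKA is the precision estimate.

# Global kinetic analysis (GKA)

`global_fit()` uses variable projection: for a trial of the $n + 2$
nonlinear parameters ($\log\tau_1,\dots,\log\tau_n$, $t_0$,
$\log\mathrm{fwhm}$), the DADS are the per-wavelength weighted
least-squares solution against the convolved-exponential basis, and
Levenberg–Marquardt (minpack.lm) minimizes the projected residual.
Log-parameterization enforces positivity and conditions the search;
lifetimes are bounded to $[10^{-3}, 10^4]$ ps. Adjacent fitted lifetimes
closer than a factor 1.05 trigger a degeneracy warning and an automatic
refit with $n-1$ components. A single global $t_0$/width is fitted —
chirp is corrected beforehand, so residual wavelength dependence of time
zero is below the delay step.

The number of components is suggested by `svd_rank()`: SVD of the
noise-whitened matrix, counting singular values above the
Gavish–Donoho optimal hard threshold
$\lambda^*(\beta)\sqrt{Q}\,\hat\sigma$ (aspect ratio $\beta$, unit noise
$\hat\sigma$ estimated from the median singular value against the
Marchenko–Pastur median). The threshold sits $\sim$15% above the bulk
edge $\sqrt{n_t}+\sqrt{n_\lambda}$, which makes the count robust to
Tracy–Widom edge fluctuations and to sampling error in the baseline
noise estimates; the bare bulk edge was measured to over-count on pure
noise.

Sequential-model quantities are analytic. With rates $k_l = 1/\tau_l$,
the concentrations of $1 \to 2 \to \dots \to n$ are
$c_l = \sum_{j\le l} b_{jl}\, c_{k_j}$ with the Bateman coefficients
$b_{jl}$, each mode convolved with the same Gaussian IRF. EADS solve
$\mathrm{DADS} = B\,\mathrm{EADS}$ exactly (upper-triangular $B$), which
implies the sum rule $\mathrm{EADS}_1 = \sum_k \mathrm{DADS}_k$ and
bit-level agreement of the DADS- and EADS-reconstructed surfaces.
Duplicate rates make $B$ singular and are an error by design, not a
limit evaluation. Components faster than 0.15 ps are reported but
flagged as lying within the IRF time scale.

# Fluorescence reconvolution

`reconvolution_fit()` models counts as
$b + s\sum_i A_i\, c_{\tau_i}(t)$ with weights $1/\max(\mathrm{counts},
1)$ — the standard TCSPC compromise that keeps empty bins from blowing
up the Poisson weight. The linear part (component coefficients plus
background) is solved per trial by weighted least squares with an
active-set nonnegativity constraint on the components; amplitudes are
reported as fractions summing to one, so they are invariant under count
rescaling. Gaussian IRFs use the closed-form convolution and support
log-spaced delay axes (gate-scanned upconversion) directly, fitted
as-is with per-point weights; measured-trace IRFs use discrete
convolution on a uniform axis with a fitted sub-bin shift (linear
interpolation), since detector color shift is real in TCSPC.
`component_table()` flags any lifetime strictly below the IRF FWHM as
within the instrument response.

# The synthetic-data generator

`simulate_ta()` implements the forward model the analyses assume:
parallel (DADS) or sequential (EADS) kinetics convolved with the
Gaussian IRF, per-wavelength time zero $t_0(\lambda)$ from a cubic
polynomial in normalized wavelength (a smooth monotone stand-in for
supercontinuum dispersion), a Gaussian-in-time coherent artifact riding
on $t_0(\lambda)$, and additive Gaussian noise (homoscedastic by
default, per-wavelength sd optional) drawn from a single seed.
`fcc_like_spec()` fixes the standard test conditions: 80 wavelengths
over 290–1000 nm; a fast component pairing a ground-state-bleach trough
near 410 nm with excited-state absorption near 430 and 700 nm; a slower
component with a narrower 408/430 nm derivative-shaped pair; 0.10 ps
IRF; noise scaled to 2% of the clean-signal peak. The delay grid uses
20 fs linear steps across $\pm$0.5 ps and 20 points/decade to 1 ns
(117 delays), the sampling pattern of a typical broadband TA
acquisition.

What it does *not* emulate: solvent Raman and cross-phase-modulation
fine structure (the artifact is a plain time-Gaussian — its functional
form is not specified by typical experiments either), anisotropy
(magic-angle acquisition is assumed), pump scatter, detector
heteroscedasticity beyond the optional per-wavelength sd, and $1/f$
drifts. Passing tests on these synthetics therefore demonstrate
correctness of the inference chain under its own model assumptions, not
robustness to every instrumental pathology.

# Preprocessing choices

* **Chirp.** Time zero per wavelength is the centroid of the
  noise-floor-subtracted squared slope (3-step central differences) in a
  $\pm$0.25 ps window around the maximum-|slope| delay. The squared
  slope of both an IRF edge and a symmetric artifact is symmetric about
  $t_0$, so the centroid is unbiased for either feature, where the raw
  argmax is displaced by $\pm\sigma_\mathrm{artifact}$ at
  artifact-dominated wavelengths. The cubic dispersion fit is weighted
  by per-column slope power so signal-free wavelengths do not drag it.
  Correction shifts each column by linear interpolation (higher-order
  splines ring at the artifact), filling out-of-range cells with the
  column's pre-zero baseline mean.
* **Log averaging** bins delays beyond the linear window into
  log-uniform bins (arithmetic mean of rows, geometric-mean bin delay —
  the unbiased placement on a log axis); data already log-spaced at the
  target density pass through unchanged.
* **Noise** is the per-wavelength baseline sd over delays earlier than
  $-2\times$FWHM (at least 5 required), floored at $10^{-6}$ mOD, and
  weights the $\chi^2$ of both fits.

# Problem sizes and determinism

The test suite and the acceptance script run desk-scale problems: the
standard matrix is $117 \times 80$, the lifetime grid 95 points, the
regularization ladder 25–49 fits, all in a few minutes on one CPU. All
randomness flows through explicit integer seeds (`withr::with_seed`), so
every simulation is bit-reproducible; fitted quantities are
deterministic given the data.

# Known limitations

* CSV matrix layout only (see `?read_matrix`); no vendor formats.
* No branched or reversible kinetic schemes, no anisotropy, no error
  bars on the lifetime density map, no wavelength-coupled (2-D)
  regularization.
* The entropy functional follows the signed-amplitude form documented
  above; other maxent variants (positive-only, different priors) would
  give different density shapes, though the located peak centers should
  agree at the grid-step level.
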