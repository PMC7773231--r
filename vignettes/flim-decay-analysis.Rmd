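---
title: "Models and methods for FLIM decay analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for FLIM decay analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimfit)
```

This vignette documents the statistical models, numerical conventions and
design choices behind the package's estimators, in the spirit of a methods
section: what is fitted, under which assumptions, which knobs matter, and
what the synthetic validation does and does not demonstrate.

## The data model

A TCSPC acquisition bins photon arrival times into `n` bins of width
`Δt` (a `time_grid`).  One pixel's histogram is a `decay_curve`; an
acquisition is a `flim_image` with axes (time, y, x).  Counts are
Poisson: bin `i` holds `y_i ~ Poisson(f_i)` independently, where `f_i`
is the expected decay.  Two decay laws are supported:

* multi-exponential: `f(t) = Z + Σ_i A_i exp(−t/τ_i)`,
* stretched exponential: `f(t) = Z + A exp(−(t/τ)^(1/h))`,

with `Z` a constant background (ambient light, dark counts), `A_i`
amplitudes in counts, `τ_i` lifetimes in ns, and `h` a heterogeneity
parameter (`h = 1` recovers the mono-exponential).

Three conventions are fixed package-wide and matter for
cross-implementation comparisons:

1. **Bin centres.** Models are evaluated at bin centres,
   `t_j = (j + ½)Δt`.  Acquisition hardware does not specify where in a
   bin its counts "live"; the centre convention makes the closed-form RLD
   estimator, the LM fitter, and the phasor transform mutually consistent
   and makes noiseless recovery exact, which is the property our oracle
   tests rely on.
2. **Time restarts at the fit range.** A `fit_range` is a half-open
   interval `[start_bin, end_bin)` of 0-based indices, and `t = 0` at
   the leading edge of `start_bin`.  Amplitudes therefore refer to the
   start of the fitted window.
3. **Indices are 0-based and half-open** in all file formats and ranges,
   matching how the data are laid out on disk rather than R's 1-based
   vectors (the constructors translate).

When a measured instrument response (IRF, "prompt") is supplied, the
model curve is replaced at every iteration by the discrete causal
convolution of the decay part with the unit-sum-normalised IRF, with `Z`
added afterwards (iterative reconvolution).  Normalising the IRF keeps
amplitudes in count units.  The convolution is the direct `O(n²)` sum
(vectorised over the IRF's support); an FFT path would change nothing at
`n ≤ 512` and the direct form is easier to reason about near the window
edges.

## Noise models and objectives

Five noise models control the fit objective:

| kind | per-bin variance | notes |
|---|---|---|
| `constant` | `σ²` (user supplied) | unweighted least squares up to scale |
| `given` | user-supplied vector | e.g. from detector calibration |
| `gaussian` | `max(y_i, 1)` | variance floor avoids divide-by-zero on empty bins |
| `poisson` | `max(y_i, 15)` | Gaussian approximation to Poisson; 15 counts² is the point below which that approximation degrades |
| `mle` | — | Poisson deviance, no weights |

The weighted kinds minimise `χ² = Σ (y_i − f_i)²/σ_i²`; `mle` minimises
the Poisson deviance `D = 2Σ[f_i − y_i + y_i ln(y_i/f_i)]` (the `y_i = 0`
term is its limit `2f_i`), equivalent to maximising the Poisson
likelihood.  The reduced χ² reported with every fit divides by
`n_points − n_free`.

A practical point the test suite quantifies: weighting by a function of
the *measured* counts (the `gaussian`/`poisson` kinds) anti-correlates
weights with noise and biases estimates low at low counts (the classical
Neyman-χ² effect; ≈ −1% on τ at 10⁴ photons under `poisson`, much worse
under `gaussian`).  The reported standard errors remain well calibrated —
the ensemble spread matches the mean reported error — but coverage of the
truth is shifted by the bias.  The `mle` kind has no such bias and is the
right choice when counts are low; the coverage property (truth inside
±1σ in ≈ 68% of replicates) is therefore asserted under `mle`.

## Rapid lifetime determination

`fit_rld` splits the (truncated-to-3m-bins) range into thirds with sums
`S1, S2, S3`.  For a sampled mono-exponential with `r = exp(−Δt/τ)`,

    S2 − S1 = −A √r (1 − r^m)² / (1 − r),      S3 − S2 = (S2 − S1)·r^m,

so `x = (S3−S2)/(S2−S1) = r^m` exactly, giving `τ = −mΔt/ln x`, then `A`
and `Z` by the same discrete geometric identities.  Because the algebra
is exact for bin-centre sampling, noiseless recovery is exact to machine
precision — a much stronger invariant than the continuous-integral
variant provides, and the reason the discrete back-solve was chosen.
Leftover bins (range not divisible by 3) are dropped from the tail to
keep the integrals equal-width.  Flat or rising transients (integral
differences of opposite sign, or a ratio outside (0,1)) raise a
non-convergence error.

Under noise, `τ̂` inherits the nonlinearity of `1/ln(x)`: second-order
propagation gives a positive bias `≈ τ²σ²_x/(mΔt·x)²`-order, about +4%
at 5,000 photons for lifetimes late in a 10 ns window.  This is an
estimator property, not an implementation defect; spatial binning (below)
suppresses it by raising the photon count per fitted transient.

## Levenberg–Marquardt fitting

`fit_lma` is a classical damped Gauss–Newton loop: the damping factor
starts at 1e−3, is multiplied by 10 on a rejected step and divided by 10
on an accepted one; the damped normal equations use Marquardt scaling
(diagonal inflation).  Convergence is declared when an accepted step's
relative objective decrease falls below `tol` (default 1e−6), or when
the damping exceeds 1e10 (the step has collapsed to zero).  Analytic
derivatives are used for multi-exponential models — each basis column is
convolved with the IRF when reconvolution is active, the offset column
is not — and central finite differences (relative step 1e−6) for the
stretched exponential, whose `h` derivative has no convenient closed
form.  The MLE objective reuses the same machinery through its
Gauss–Newton approximation (curvature weights `y/f²`, gradient weights
`y/f − 1`), which is the standard transformed-residual treatment.

Parameters may be fixed (by name, optionally at a given value, e.g.
`fixed = c(Z = 0)`) or restrained to a box; restraints are enforced by
projection (clamping after each step) rather than penalties, which keeps
the LM acceptance logic untouched.  Initial estimates default to the RLD
closed form; a `k`-component request splits the RLD lifetime
geometrically (`τ/2, 2τ, …`) with the amplitude divided equally, and a
flat-curve fallback (extrema heuristic, lifetime = range/4) guarantees an
initial value always exists.

Standard errors come from the inverse curvature ("alpha") matrix at the
optimum; for the weighted kinds a copy scaled by `√(reduced χ²)` is the
headline `std_errors` and the unscaled matrix-only version is kept in
`std_errors_raw`, since conventions differ between packages and the
scaled version is the safer default when the noise model is only
approximate.

### Offset degeneracy on short windows

On a 10 ns window a 4–6 ns decay falls by less than `e^{−2.5}`, so a
free offset is nearly collinear with the decay itself and the joint
`(Z, τ)` fit is statistically degenerate: the free-offset estimate
trades background against lifetime and is several σ low even though it
attains a lower χ².  The validation protocol therefore fixes the offset
at its known value and fits lifetime and amplitude only — the same
protocol used for fluorescence-standard comparisons — and the package
exposes it as `fit_config(fixed = c(Z = 0))`.

## Global analysis

`fit_global` shares the lifetimes across all pixels while the offset and
amplitudes stay local (the offset map is per-pixel because background is
a property of the pixel, not the fluorophore).  With lifetimes fixed,
each pixel's `(Z, A_1…A_k)` is an exact weighted linear least-squares
solve against the basis `{1, exp(−t/τ_i)}`; the outer loop is LM over
the shared lifetimes minimising the summed χ².  Because the inner solves
are exact optima, the envelope property makes the outer gradient equal to
the partial derivative with amplitudes held fixed, so no amplitude
sensitivities are needed (variable projection).  Inner solves that fail
(collinear basis) mark their pixel invalid; more than 50% failures abort.
The outer loop is initialised from an LM fit of the image-summed
transient, which at typical budgets has ~10⁷–10⁸ photons and pins the
lifetimes well.  The procedure is single-threaded: unlike per-pixel
fitting it is a single coupled optimisation.

## Phasor analysis

`phasor_transform` computes the first Fourier moments of the
background-subtracted transient at the fundamental frequency of the fit
range, `ω = 2π/T`.  Tying `ω` to the range duration (rather than the
laser repetition rate) makes the truncation error cancel exactly: for
`ω` a harmonic of the window, the truncated integrals of a
mono-exponential reproduce the infinite-window closed form
`g = 1/(1+ω²τ²)`, `s = ωτ/(1+ω²τ²)` — so single-exponential pixels land
on the universal semicircle `(g−½)² + s² = ¼` up to `O(Δt²)`
discretisation and shot noise.  A repetition-rate frequency can be
supplied via `omega`; whichever is used is always reported in the output
(as `frequency_mhz`), since phasor coordinates are meaningless without
it.  Phase (`s/(ωg)`) and modulation (`√(1/(g²+s²) − 1)/ω`) lifetimes
agree for mono-exponentials and bracket mixtures.

## Bayesian estimation

`fit_bayes` targets the low-photon regime with a mono-exponential plus
uniform-background model.  Conditional on the total count `N`, bin
occupancies are multinomial with

    p_i(τ, b) = b/n + (1−b) · (e^{−t_i^{lo}/τ} − e^{−t_i^{hi}/τ}) / (1 − e^{−T/τ}),

where `b` is the background photon fraction.  The log-likelihood
`Σ y_i log p_i` is evaluated on a 200 × 200 grid — log-spaced in τ over
`(0.05 ns, 2 × range)`, uniform cell midpoints in `b` over (0, 1) — with
uniform priors over those bounds; posterior means and standard
deviations follow by grid quadrature, and both the posterior-mean and
MAP estimates are reported (the mean is the headline estimate: it
minimises posterior squared error and is smooth in the data, which is
what stabilises low-count maps).  The returned amplitude and offset are
back-computed from `N`, `b̂` and `τ̂` through the discrete geometric sum,
so the fitted curve is directly comparable with the least-squares
fitters.  This binned-multinomial construction deliberately replaces the
arrival-time machinery of the published Bayesian FLIM method: it uses
the same evidence at the granularity the data actually arrive in here
(binned histograms), at the cost of sub-bin timing information.

If more than 20% of the posterior mass falls in the boundary cells of
the τ grid, the result is flagged and a warning suggests widening
`tau_bounds`.  Mass piling up at `b = 0` is *not* warned about: for
background-free data that is the correct posterior shape, not a
misconfiguration (both boundary masses are reported in `edge_mass`).
For whole images the log-probability table depends only on the grid and
fit range, so it is built once and applied to all pixels as a matrix
product, which is what makes per-pixel Bayesian maps affordable.

## Image-level operations

`bin_image` replaces each transient by the sum over its k×k spatial
neighbourhood (zero-padded at edges), per time bin, via per-plane FFT
convolution; summing rather than averaging preserves the Poisson
interpretation of the counts, so every downstream noise model remains
valid.  A direct shift-and-add path exists and the two agree to 1e−6 —
a property the tests assert rather than assume.  `fit_image` bins,
masks pixels whose in-range photon sum is below the intensity threshold
(NaN in every map, 0 in the validity mask), and fits the rest in chunks
whose partitioning provably does not affect the result; `cores > 1`
forks chunks via the parallel package.  Mean-lifetime maps offer both
conventions — amplitude-weighted `ΣA_iτ_i/ΣA_i` (default: the fraction
of *molecules*) and intensity-weighted `ΣA_iτ_i²/ΣA_iτ_i` (the fraction
of *photons*) — because instrument vendors disagree and the choice
changes mixture values.  FRET efficiency is `1 − τ_DA/τ_D`, accepting
scalars or maps.

## The synthetic validation data, and what it shows

The generators reproduce the package's validation conditions: a
32-level lifetime sweep (0.2–6.0 ns, equal row-major blocks, uniform
5,000-photon budget, 256 bins over 10 ns), a 128 × 128 two-component
mixture (0.4 and 2.1 ns — the classic free/bound NAD(P)H-like pair) whose
species-A fraction grades linearly in `x + y` from pure A at the
top-left to pure B at the bottom-right, and binomial photon thinning in
the nine fractions 10%–90% for low-light comparisons.  Where the studies
left a quantity unstated, a value was fixed once: 5,000 expected photons
per pixel (a typical single-frame TCSPC budget), linear rather than
radial fraction gradient, equal rectangular level blocks.  All
generators are pure functions of their parameters and seed.

What the simulations deliberately omit: IRF distortion (unless an IRF is
passed explicitly), detector afterpulsing, dark-count structure beyond a
constant `Z`, pile-up, spatial intensity variation, and spectral
bleed-through.  Passing the validation suite therefore demonstrates the
*estimators* — recovery, calibration, ordering of methods under photon
starvation — under ideal Poisson statistics, not robustness to every
instrumental artefact of real hardware.

Validation protocol details, fixed as the package's own choices: the
sweep and fluorescein ensembles are fitted with the offset fixed at its
true value (see the degeneracy note above); sweep images are analysed
with the standard 3 × 3 binning kernel before per-pixel fitting; sweep
slopes regress per-level mean estimates on truth.  Problem sizes in the
acceptance script: the mixture recovery and sweep at the full 128 × 128,
the fluorescein ensemble at n = 200 transients; the test suite runs the
same protocols with the mixture at 64 × 64 and the photon-starvation
comparison at four lifetime levels × 200 pixels.

## Numerical details and limitations

* LM tolerance 1e−6 (relative objective change), max 100 iterations;
  singular curvature during iteration is an error naming the parameter
  without leverage; singularity only at the final error-estimate stage
  degrades to `NA` errors with a warning.
* Invalid parameter regions (τ ≤ 0, h ≤ 0, non-positive MLE model) are
  handled by step rejection, not error, so the optimiser can back off.
* FFT binning clamps the tiny negative round-off (~1e−13) to zero to
  preserve the non-negativity invariant of counts.
* TIFF storage: integer stacks ≤ 65535 are written losslessly as uint16;
  anything else as float32 rescaled into [0,1] with the scale in the JSON
  sidecar.  Parameter maps are affine-encoded into [0.25, 1] with 0
  reserved for invalid pixels; float32 limits round-trips to ~7
  significant digits.
* RLD requires a decaying signal in all three integration windows; very
  short lifetimes relative to the window leave the later thirds empty
  and the estimator (correctly) refuses.  Per-pixel maps record such
  pixels as NaN.
* The Bayes estimator is mono-exponential only; applying it to mixtures
  returns a well-defined but model-misspecified average lifetime.
* Global analysis assumes the component lifetimes really are shared;
  spatial lifetime gradients violate the model and surface as structured
  χ² maps rather than errors.
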