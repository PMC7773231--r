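# flimfit

Fitting and analysis of time-domain fluorescence lifetime imaging (FLIM)
data in R.

FLIM instruments based on time-correlated single-photon counting (TCSPC)
record, for every image pixel, a histogram of photon arrival times — a
*decay curve* or *transient*.  The physics of fluorescence makes the
ideal transient a sum of exponential decays,

    y(t) = Z + Σᵢ Aᵢ · exp(−t / τᵢ)

(optionally a stretched exponential `Z + A·exp(−(t/τ)^(1/h))`), distorted
in practice by the instrument response function (IRF) and by Poisson
photon-counting noise.  The lifetimes τᵢ report on the fluorophore's
microenvironment (FRET, pH, viscosity, metabolic state), so extracting
them reliably — per pixel, across a 256 × 256 image, often at low photon
counts — is the central computational problem of FLIM.  This package is
for microscopists and image-analysis developers who need those estimators
scriptable in R, end to end: from a raw count stack to per-pixel
parameter maps.

## What it implements

- **RLD** (`fit_rld`) — rapid lifetime determination from three
  contiguous integrals; a closed form that is exact on noiseless sampled
  mono-exponentials and serves as the default initialiser.
- **Levenberg–Marquardt** (`fit_lma`) — multi-exponential and
  stretched-exponential least squares with selectable noise models
  (constant / given / Gaussian / Poisson — the latter a Gaussian
  approximation with variance floored at 15 counts² — and true Poisson
  MLE via the deviance), parameter fixing and box restraints, error
  estimates from the curvature (alpha) matrix, and optional iterative
  reconvolution against a measured IRF.
- **Global analysis** (`fit_global`) — image-wide shared lifetimes with
  per-pixel offset and amplitudes, solved by variable projection.
- **Phasor** (`phasor_transform`) — fit-free frequency-domain estimates
  (g, s) with phase and modulation lifetimes on the universal circle.
- **Bayesian estimation** (`fit_bayes`) — grid-based posterior for
  mono-exponential decays with a uniform background fraction, robust at
  very low photon counts.
- **Image operations** (`fit_image`, `bin_image`, `crop_image`,
  `mean_lifetime_map`, `fret_efficiency`) — spatial binning by FFT
  convolution, intensity thresholding, chunked per-pixel fitting,
  mean-lifetime and FRET-efficiency maps.
- **Synthetic data** (`simulate_transient`, `simulate_onecomp_image`,
  `simulate_twocomp_image`, `thin_photons`) — seeded Poisson generators
  reproducing the validation studies, including binomial photon
  thinning.
- **I/O and CLI** — multi-page TIFF + JSON sidecar stacks, CSV
  transients, float-TIFF parameter maps with a JSON manifest, and a
  command-line wrapper (`inst/cli/flimfit`) with `simulate`, `fit-*` and
  `fret` subcommands.

## Worked example

Simulate a fluorescein-like transient (τ = 4 ns, 10,000 photons over a
10 ns window of 256 bins) and fit it with the offset fixed, then compare
with the fit-free phasor estimate:

```r
library(flimfit)
g   <- time_grid(256, 10 / 256)          # 256 bins, 39 ps each
d   <- simulate_transient(decay_model(Z = 0, A = 1, tau = 4.0), g,
                          total_photons = 10000, seed = 11)
fit <- fit_lma(d, fit_config(fixed = c(Z = 0)))
summary(fit)
#> Decay fit by 'lma'
#>      Estimate Std. Error
#> Z       0.000          -
#> A1    102.271      1.548
#> tau1    4.052      0.064
#> Reduced chi-squared: 0.8508 on 254 degrees of freedom
#> Iterations: 3 (converged)

phasor_transform(d)
#> <flim_phasor> g = 0.1289, s = 0.3437 (100 MHz)
#>   tau_phase = 4.243 ns, tau_mod = 4.033 ns
```

The fitted lifetime (4.05 ± 0.06 ns) recovers the 4.0 ns truth within
one standard error; a reduced χ² near 1 says the Poisson noise model
describes the residuals.  The phasor point lies on the universal circle
(its phase and modulation lifetimes agree within noise), as expected for
a mono-exponential decay.

FRET efficiency from donor lifetimes is one line:

```r
fret_efficiency(2.23, 2.16)
#> <flim_fret> T_D = 2.23 ns, T_DA = 2.16 ns, efficiency = 3.14%
```

For whole images, `fit_image` returns per-parameter maps:

```r
sim  <- simulate_twocomp_image(seed = 1)          # 128 x 128, 0.4/2.1 ns
maps <- fit_image(sim$image, "global", n_components = 2)
maps$global$global_tau                            # shared lifetimes
```

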