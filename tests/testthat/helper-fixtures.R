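# Shared fixture builders for the test suite.  Everything is generated in
# code; no binary fixtures on disk.

# Noiseless sampled decay: model evaluated at bin centres.
noiseless_decay <- function(Z, A, tau, grid) {
  decay_curve(eval_model(decay_model(Z = Z, A = A, tau = tau), grid), grid)
}

# Default 10 ns / 256 bin acquisition used throughout the validation
# studies.
std_grid <- function(n_bins = 256L) time_grid(n_bins, 10 / n_bins)

# A narrow Gaussian prompt centred early in the window.
gaussian_irf <- function(grid, center_ns = 0.5, sd_ns = 0.1) {
  t <- bin_centers(grid)
  flim_irf(exp(-(t - center_ns)^2 / (2 * sd_ns^2)), grid)
}

# Small multi-level test image: `npx_per_level` pixels per lifetime,
# arranged in rows, uniform photon budget.
level_image <- function(taus, npx_per_level, grid, photons, seed) {
  n_lev <- length(taus)
  w <- npx_per_level
  counts <- array(0, dim = c(grid$n_bins, n_lev, w))
  set.seed(seed)
  for (l in seq_len(n_lev)) {
    mu <- flimfit:::expected_transient(
      decay_model(Z = 0, A = 1, tau = taus[l]), grid, photons)
    counts[, l, ] <- stats::rpois(grid$n_bins * w, mu)
  }
  list(image = flim_image(counts, grid),
       level = matrix(rep(seq_len(n_lev), times = w), n_lev, w))
}
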