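#' Simulate a single TCSPC transient
#'
#' Generates one decay curve by evaluating the model over the full grid
#' (optionally convolving with an IRF), rescaling the expected curve so
#' that its sum equals `total_photons`, and drawing independent Poisson
#' counts per bin.  The same seed always reproduces the same counts.
#'
#' @param spec a [decay_model()].
#' @param grid a [time_grid()].
#' @param total_photons positive expected total photon count (0 is allowed
#'   only with `poisson = FALSE`, giving the degenerate all-zero curve).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param irf optional [flim_irf()] convolved with the decay part of the
#'   model (the offset Z is excluded from convolution).
#' @param poisson draw Poisson counts (`TRUE`, default) or return the
#'   noiseless expected curve.
#' @return a [decay_curve()].
#' @examples
#' g <- time_grid(64, 10 / 64)
#' simulate_transient(decay_model(Z = 0, A = 1, tau = 2), g, 1000, seed = 1)
#' @export
simulate_transient <- function(spec, grid, total_photons, seed = NULL,
                               irf = NULL, poisson = TRUE) {
  stopifnot(inherits(spec, "flim_model"), inherits(grid, "flim_grid"))
  if (!is.finite(total_photons) || total_photons < 0 ||
      (total_photons == 0 && poisson))
    stop("'total_photons' must be positive (0 only when poisson = FALSE)")
  mu <- expected_transient(spec, grid, total_photons, irf)
  counts <- if (poisson) with_seed(seed, stats::rpois(grid$n_bins, mu)) else mu
  decay_curve(counts, grid)
}

# Expected (noise-free) transient scaled to a photon budget.
expected_transient <- function(spec, grid, total_photons, irf = NULL) {
  mu <- eval_model(spec, grid)
  if (!is.null(irf)) {
    mu <- convolve_with_irf(mu - spec$Z, irf) + spec$Z
  }
  if (any(mu < 0)) stop("expected curve has negative values")
  s <- sum(mu)
  if (s <= 0) {
    if (total_photons == 0) return(mu)
    stop("model curve sums to zero; cannot scale to a photon budget")
  }
  mu * (total_photons / s)
}

#' Simulate the one-component lifetime-sweep validation image
#'
#' Builds an image whose pixels take `n_levels` evenly spaced true
#' lifetimes between `tau_min` and `tau_max`, arranged as equal contiguous
#' blocks in row-major order (with the default 128 x 128 image and 32
#' levels each block is a 4-row strip).  Every pixel receives an
#' independent Poisson realisation of a mono-exponential decay with the
#' same expected photon budget.
#'
#' @param tau_min,tau_max sweep endpoints in ns; `tau_max` must fit inside
#'   the grid's time range.
#' @param n_levels number of distinct lifetimes (at least 2).
#' @param grid a [time_grid()]; default 256 bins spanning 10 ns.
#' @param photons_per_pixel expected photons per pixel.
#' @param size image size `c(height, width)`.
#' @param seed optional integer seed.
#' @param poisson draw Poisson counts (default) or store the noiseless
#'   expected curves.
#' @return list with elements `image` (a [flim_image()]) and `truth`
#'   (per-pixel true `tau` map, `level` index map, the level lifetimes,
#'   `total_photons` map, `seed`, `photon_fraction = 1`).
#' @export
simulate_onecomp_image <- function(tau_min = 0.2, tau_max = 6.0,
                                   n_levels = 32,
                                   grid = time_grid(256, 10 / 256),
                                   photons_per_pixel = 5000,
                                   size = c(128, 128), seed = NULL,
                                   poisson = TRUE) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2) stop("'n_levels' must be at least 2")
  if (tau_max >= grid$n_bins * grid$bin_width_ns)
    stop("'tau_max' must be smaller than the grid's time range")
  if (any(size < 1)) stop("invalid image size")
  h <- as.integer(size[1]); w <- as.integer(size[2])
  taus <- seq(tau_min, tau_max, length.out = n_levels)
  npix <- h * w
  # row-major contiguous blocks: pixel p (row-major) gets level floor(p*L/N)
  p <- seq_len(npix) - 1L
  level_rm <- pmin(n_levels - 1L, (p * n_levels) %/% npix) + 1L
  level <- matrix(0L, h, w)
  level[cbind(rep(seq_len(h), each = w), rep(seq_len(w), times = h))] <- level_rm
  tau_map <- matrix(taus[level], h, w)
  counts <- array(0, dim = c(grid$n_bins, h, w))
  with_seed(seed, {
    for (lev in seq_len(n_levels)) {
      mu <- expected_transient(decay_model(Z = 0, A = 1, tau = taus[lev]),
                               grid, photons_per_pixel)
      idx <- which(level == lev, arr.ind = TRUE)
      draws <- if (poisson) stats::rpois(grid$n_bins * nrow(idx), mu)
               else rep(mu, times = nrow(idx))
      dim(draws) <- c(grid$n_bins, nrow(idx))
      for (j in seq_len(nrow(idx)))
        counts[, idx[j, 1], idx[j, 2]] <- draws[, j]
    }
  })
  list(image = flim_image(counts, grid),
       truth = list(tau = tau_map, level = level, tau_levels = taus,
                    total_photons = matrix(photons_per_pixel, h, w),
                    seed = seed, photon_fraction = 1))
}

#' Simulate the two-component mixture validation image
#'
#' Two fluorescent species with fixed lifetimes (defaults 0.4 ns and
#' 2.1 ns) are mixed with a species-A photon fraction that grades linearly
#' in `(x + y)` from 1 at the top-left corner to 0 at the bottom-right
#' corner, so the top-left pixel is pure species A and the bottom-right
#' pixel pure species B.  Every pixel has the same expected photon budget.
#'
#' @param tau length-2 vector of component lifetimes (ns); component 1 is
#'   species A.
#' @param size image size `c(height, width)`, at least 2 x 2.
#' @param photons_per_pixel expected photons per pixel.
#' @param grid a [time_grid()].
#' @param Z constant background offset added per bin (counts), default 0.
#' @param seed optional integer seed.
#' @param poisson draw Poisson counts (default) or store the noiseless
#'   expected curves.
#' @return list with `image` and `truth`; the truth holds the species-A
#'   photon `fraction` map, per-pixel model amplitude maps `A1`, `A2`, the
#'   shared `tau`, `Z`, and the photon budget map.
#' @export
simulate_twocomp_image <- function(tau = c(0.4, 2.1), size = c(128, 128),
                                   photons_per_pixel = 5000,
                                   grid = time_grid(256, 10 / 256),
                                   Z = 0, seed = NULL, poisson = TRUE) {
  if (length(tau) != 2 || tau[1] == tau[2] || any(tau <= 0))
    stop("'tau' must be two distinct positive lifetimes")
  if (any(size < 2)) stop("image must be at least 2 x 2")
  h <- as.integer(size[1]); w <- as.integer(size[2])
  xi <- matrix(rep(seq_len(w) - 1L, each = h), h, w)
  yi <- matrix(rep(seq_len(h) - 1L, times = w), h, w)
  frac <- 1 - (xi + yi) / ((w - 1) + (h - 1))
  # normalised per-species bin probabilities over the grid
  p1 <- expected_transient(decay_model(Z = 0, A = 1, tau = tau[1]), grid, 1)
  p2 <- expected_transient(decay_model(Z = 0, A = 1, tau = tau[2]), grid, 1)
  n <- grid$n_bins
  decay_photons <- photons_per_pixel - Z * n
  if (decay_photons <= 0) stop("'Z' background exceeds the photon budget")
  # expected stack: outer product of bin probabilities with pixel budgets
  fv <- as.vector(frac)
  mu <- outer(p1, fv * decay_photons) + outer(p2, (1 - fv) * decay_photons) + Z
  counts <- if (poisson) with_seed(seed, stats::rpois(length(mu), mu))
            else mu
  dim(counts) <- c(n, h, w)
  # true amplitudes at bin centres: sum_j A r^(j+1/2) = photons per species
  amp <- function(fphot, tau_i) {
    r <- exp(-grid$bin_width_ns / tau_i)
    fphot * (1 - r) / (sqrt(r) * (1 - r^n))
  }
  list(image = flim_image(counts, grid),
       truth = list(fraction = frac, tau = tau, Z = Z,
                    A1 = amp(frac * decay_photons, tau[1]),
                    A2 = amp((1 - frac) * decay_photons, tau[2]),
                    total_photons = matrix(photons_per_pixel, h, w),
                    seed = seed, photon_fraction = 1))
}

#' Binomial photon thinning
#'
#' Retains each recorded photon independently with probability `fraction`
#' (binomial thinning per bin), emulating a shorter acquisition.  Thinning
#' a Poisson-count curve yields Poisson counts with mean scaled by
#' `fraction`.
#'
#' @param x a [decay_curve()] or [flim_image()] with integer counts.
#' @param fraction retention probability in (0, 1]; 1 returns the input
#'   unchanged.
#' @param seed optional integer seed.
#' @return object of the same class as `x`.
#' @export
thin_photons <- function(x, fraction, seed = NULL) {
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]")
  if (fraction == 1) return(x)
  counts <- x$counts
  if (any(counts != round(counts)))
    stop("photon thinning requires integer counts")
  thinned <- with_seed(seed,
    stats::rbinom(length(counts), size = as.integer(round(counts)),
                  prob = fraction))
  if (inherits(x, "flim_decay")) {
    decay_curve(thinned, x$grid)
  } else if (inherits(x, "flim_image")) {
    dim(thinned) <- dim(counts)
    flim_image(thinned, x$grid)
  } else stop("'x' must be a flim_decay or flim_image")
}

#' Photon-fraction ladder
#'
#' The nine retention fractions 0.1, 0.2, ..., 0.9 used by the
#' low-photon validation study.
#'
#' @return numeric vector of length 9.
#' @export
photon_fraction_ladder <- function() seq(0.1, 0.9, by = 0.1)
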