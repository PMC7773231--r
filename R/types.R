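#' Time axis of a TCSPC acquisition
#'
#' A `flim_grid` describes the uniform time axis shared by a decay curve,
#' an image stack and an instrument response function: the number of time
#' bins, the bin width in nanoseconds, and the time of the leading edge of
#' bin 0.  Model curves are always evaluated at bin centres,
#' `origin_ns + (j + 0.5) * bin_width_ns` for bin `j` (0-based).
#'
#' @param n_bins positive integer, number of time bins (at least 3).
#' @param bin_width_ns positive numeric, width of one bin in nanoseconds.
#' @param origin_ns time (ns) of the leading edge of bin 0.
#' @return An object of class `flim_grid`.
#' @examples
#' g <- time_grid(256, 10 / 256)
#' bin_centers(g)[1:3]
#' @export
time_grid <- function(n_bins, bin_width_ns, origin_ns = 0) {
  n_bins <- as.integer(n_bins)
  if (length(n_bins) != 1L || is.na(n_bins) || n_bins < 3L)
    stop("'n_bins' must be a single integer >= 3")
  if (!is.numeric(bin_width_ns) || length(bin_width_ns) != 1L ||
      !is.finite(bin_width_ns) || bin_width_ns <= 0)
    stop("'bin_width_ns' must be a single positive number")
  if (!is.numeric(origin_ns) || length(origin_ns) != 1L || !is.finite(origin_ns))
    stop("'origin_ns' must be a single finite number")
  structure(list(n_bins = n_bins, bin_width_ns = as.numeric(bin_width_ns),
                 origin_ns = as.numeric(origin_ns)),
            class = "flim_grid")
}

#' Bin-centre times of a time grid
#'
#' @param grid a [time_grid()].
#' @param fit_range optional [fit_range()]; when given, times are restricted
#'   to the range and measured from the leading edge of its first bin (the
#'   convention used by every fitter in this package).
#' @return numeric vector of times in nanoseconds.
#' @export
bin_centers <- function(grid, fit_range = NULL) {
  stopifnot(inherits(grid, "flim_grid"))
  if (is.null(fit_range))
    return(grid$origin_ns + (seq_len(grid$n_bins) - 0.5) * grid$bin_width_ns)
  fit_range <- check_fit_range(fit_range, grid$n_bins)
  n <- fit_range$end_bin - fit_range$start_bin
  (seq_len(n) - 0.5) * grid$bin_width_ns
}

#' @export
print.flim_grid <- function(x, ...) {
  cat(sprintf("<flim_grid> %d bins x %.6g ns (range %.6g ns, origin %.6g ns)\n",
              x$n_bins, x$bin_width_ns, x$n_bins * x$bin_width_ns, x$origin_ns))
  invisible(x)
}

#' Single-pixel decay curve
#'
#' Photon counts per time bin for one transient, on a [time_grid()].
#'
#' @param counts numeric vector of non-negative photon counts, one per bin.
#' @param grid a [time_grid()] with `n_bins == length(counts)`.
#' @return An object of class `flim_decay` with fields `grid` and `counts`.
#' @examples
#' g <- time_grid(64, 0.1)
#' d <- decay_curve(rpois(64, 50), g)
#' @export
decay_curve <- function(counts, grid) {
  stopifnot(inherits(grid, "flim_grid"))
  counts <- as.numeric(counts)
  if (length(counts) != grid$n_bins)
    stop(sprintf("length(counts) == %d but grid has %d bins",
                 length(counts), grid$n_bins))
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  structure(list(grid = grid, counts = counts), class = "flim_decay")
}

#' @export
print.flim_decay <- function(x, ...) {
  cat(sprintf("<flim_decay> %d bins, %.6g ns/bin, %.0f photons total\n",
              x$grid$n_bins, x$grid$bin_width_ns, sum(x$counts)))
  invisible(x)
}

#' @export
plot.flim_decay <- function(x, log = "", ...) {
  graphics::plot(bin_centers(x$grid), x$counts, type = "h", log = log,
                 xlab = "time (ns)", ylab = "counts", ...)
  invisible(x)
}

#' Time-resolved image stack
#'
#' A 3-D stack of photon counts with dimensions (time, y, x), all pixels
#' sharing one [time_grid()].
#'
#' @param counts 3-D numeric array, first dimension of length `grid$n_bins`.
#' @param grid a [time_grid()].
#' @return An object of class `flim_image`.
#' @export
flim_image <- function(counts, grid) {
  stopifnot(inherits(grid, "flim_grid"))
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("'counts' must be a 3-D array (time, y, x)")
  storage.mode(counts) <- "double"
  if (dim(counts)[1] != grid$n_bins)
    stop(sprintf("first array dimension is %d but grid has %d bins",
                 dim(counts)[1], grid$n_bins))
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  structure(list(grid = grid, counts = counts), class = "flim_image")
}

#' @export
print.flim_image <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<flim_image> %d x %d pixels, %d time bins (%.6g ns/bin)\n",
              d[2], d[3], d[1], x$grid$bin_width_ns))
  invisible(x)
}

#' Instrument response function
#'
#' The measured system response to an instantaneous emission (the "prompt"),
#' on the same time grid as the data it is convolved with.  The curve is
#' normalised to unit sum internally before convolution so that fitted
#' amplitudes keep photon-count units.
#'
#' @param counts numeric vector of non-negative values with at least one
#'   positive entry, or a [decay_curve()] holding a measured prompt.
#' @param grid a [time_grid()] (ignored when `counts` is a `flim_decay`).
#' @return An object of class `flim_irf`.
#' @export
flim_irf <- function(counts, grid = NULL) {
  if (inherits(counts, "flim_decay")) {
    grid <- counts$grid
    counts <- counts$counts
  }
  stopifnot(inherits(grid, "flim_grid"))
  counts <- as.numeric(counts)
  if (length(counts) != grid$n_bins)
    stop("IRF length must equal the number of grid bins")
  if (anyNA(counts) || any(counts < 0))
    stop("IRF counts must be non-negative")
  if (sum(counts) <= 0)
    stop("IRF must have at least one positive entry")
  structure(list(grid = grid, counts = counts), class = "flim_irf")
}

#' @export
print.flim_irf <- function(x, ...) {
  peak <- which.max(x$counts)
  cat(sprintf("<flim_irf> %d bins, peak at bin %d (%.4g ns)\n",
              x$grid$n_bins, peak - 1L, bin_centers(x$grid)[peak]))
  invisible(x)
}

#' Fit range over the time axis
#'
#' Half-open interval `[start_bin, end_bin)` of 0-based bin indices into
#' the time axis.  All fitters measure time from the leading edge of
#' `start_bin`, so the model parameter `t = 0` coincides with the start of
#' the fitted window.
#'
#' @param start_bin,end_bin integers, `0 <= start_bin < end_bin <= n_bins`.
#' @return An object of class `flim_range`.
#' @export
fit_range <- function(start_bin, end_bin) {
  start_bin <- as.integer(start_bin); end_bin <- as.integer(end_bin)
  if (is.na(start_bin) || is.na(end_bin) || start_bin < 0L ||
      end_bin <= start_bin)
    stop("need 0 <= start_bin < end_bin")
  structure(list(start_bin = start_bin, end_bin = end_bin),
            class = "flim_range")
}

# Resolve a fit range against a grid: NULL means the full axis; validates
# bounds and the minimum length.
check_fit_range <- function(fit_range, n_bins, min_len = 3L) {
  if (is.null(fit_range)) fit_range <- structure(
    list(start_bin = 0L, end_bin = as.integer(n_bins)), class = "flim_range")
  stopifnot(inherits(fit_range, "flim_range"))
  if (fit_range$end_bin > n_bins)
    stop(sprintf("fit range end_bin %d exceeds n_bins %d",
                 fit_range$end_bin, n_bins))
  if (fit_range$end_bin - fit_range$start_bin < min_len)
    stop(sprintf("fit range must span at least %d bins", min_len))
  fit_range
}

# 1-based R indices of the bins inside a (validated) fit range.
range_idx <- function(fit_range) {
  seq.int(fit_range$start_bin + 1L, fit_range$end_bin)
}

#' @export
print.flim_range <- function(x, ...) {
  cat(sprintf("<flim_range> bins [%d, %d) (%d bins)\n",
              x$start_bin, x$end_bin, x$end_bin - x$start_bin))
  invisible(x)
}

#' Decay model specification
#'
#' The parameter vector estimated by every fitter.  Two model kinds are
#' supported:
#' \describe{
#'   \item{`multi_exp`}{\eqn{y(t) = Z + \sum_i A_i \exp(-t/\tau_i)}}
#'   \item{`stretched_exp`}{\eqn{y(t) = Z + A \exp(-(t/\tau)^{1/h})}}
#' }
#' with `t` measured from the start of the fit range.
#'
#' @param kind `"multi_exp"` or `"stretched_exp"`.
#' @param Z constant background offset (counts per bin).
#' @param A numeric vector of component amplitudes (counts); length 1 for
#'   `stretched_exp`.
#' @param tau numeric vector of positive component lifetimes (ns).
#' @param h positive stretch parameter (`stretched_exp` only; `h = 1`
#'   reduces to a mono-exponential).
#' @return An object of class `flim_model`.
#' @examples
#' decay_model(Z = 10, A = 100, tau = 2.5)
#' decay_model("stretched_exp", Z = 0, A = 50, tau = 1.2, h = 1.5)
#' @export
decay_model <- function(kind = c("multi_exp", "stretched_exp"),
                        Z = 0, A, tau, h = 1) {
  kind <- match.arg(kind)
  A <- as.numeric(A); tau <- as.numeric(tau)
  if (length(A) != length(tau))
    stop("'A' and 'tau' must have the same length")
  if (kind == "stretched_exp" && length(tau) != 1L)
    stop("stretched_exp models have exactly one component")
  if (anyNA(tau) || any(tau <= 0))
    stop("lifetimes 'tau' must be positive")
  if (!is.finite(h) || h <= 0)
    stop("stretch parameter 'h' must be positive")
  structure(list(kind = kind, n_components = length(tau),
                 Z = as.numeric(Z), A = A, tau = tau,
                 h = as.numeric(h)),
            class = "flim_model")
}

#' @export
print.flim_model <- function(x, digits = 4, ...) {
  if (x$kind == "multi_exp") {
    cat(sprintf("<flim_model> %d-component multi-exponential\n", x$n_components))
    cat("  Z =", format(x$Z, digits = digits), "\n")
    for (i in seq_len(x$n_components))
      cat(sprintf("  A%d = %s   tau%d = %s ns\n", i,
                  format(x$A[i], digits = digits), i,
                  format(x$tau[i], digits = digits)))
  } else {
    cat("<flim_model> stretched exponential\n")
    cat(sprintf("  Z = %s  A = %s  tau = %s ns  h = %s\n",
                format(x$Z, digits = digits), format(x$A, digits = digits),
                format(x$tau, digits = digits), format(x$h, digits = digits)))
  }
  invisible(x)
}

#' Noise model for decay fitting
#'
#' Selects how per-bin variances enter the fit objective:
#' \describe{
#'   \item{`constant`}{every bin has the same supplied variance `sigma2`.}
#'   \item{`given`}{per-bin variances supplied via `variances`.}
#'   \item{`gaussian`}{variance equal to the measured count (floored at 1
#'     so empty bins do not produce infinite weights).}
#'   \item{`poisson`}{variance equal to the measured count with a lower
#'     limit of 15 counts^2 — the point below which the Gaussian
#'     approximation to Poisson statistics breaks down.}
#'   \item{`mle`}{maximum-likelihood estimation through the Poisson
#'     deviance; no per-bin variances are used (see [objective()]).}
#' }
#'
#' @param kind one of `"constant"`, `"given"`, `"gaussian"`, `"poisson"`,
#'   `"mle"`.
#' @param sigma2 positive variance for the `constant` kind.
#' @param variances positive per-bin variances for the `given` kind.
#' @return An object of class `flim_noise`.  The Poisson floor is fixed at
#'   15 and exposed as field `poisson_floor`.
#' @examples
#' noise_model("poisson")
#' noise_model("constant", sigma2 = 2)
#' @export
noise_model <- function(kind = c("poisson", "gaussian", "constant", "given",
                                 "mle"),
                        sigma2 = 1, variances = NULL) {
  kind <- match.arg(kind)
  if (kind == "constant" && (!is.finite(sigma2) || sigma2 <= 0))
    stop("'sigma2' must be a positive number")
  if (kind == "given") {
    if (is.null(variances) || anyNA(variances) || any(variances <= 0))
      stop("'given' noise requires positive per-bin variances")
    variances <- as.numeric(variances)
  }
  structure(list(kind = kind, sigma2 = as.numeric(sigma2),
                 variances = variances, poisson_floor = 15),
            class = "flim_noise")
}

#' @export
print.flim_noise <- function(x, ...) {
  extra <- switch(x$kind,
                  constant = sprintf(" (sigma2 = %g)", x$sigma2),
                  given = sprintf(" (%d per-bin variances)", length(x$variances)),
                  poisson = sprintf(" (variance floor %g)", x$poisson_floor),
                  "")
  cat(sprintf("<flim_noise> kind '%s'%s\n", x$kind, extra))
  invisible(x)
}

# Run an expression with a private, restored RNG state when seed is given.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(seed) && (!is.finite(seed) || seed != round(seed)))
    stop("'seed' must be an integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
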