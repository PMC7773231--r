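#' Evaluate a decay model over a fit range
#'
#' Computes the model curve at every bin centre inside the fit range, with
#' time measured from the leading edge of the first bin in the range (the
#' shared convention that makes RLD, Levenberg-Marquardt and phasor
#' estimates mutually consistent and makes noiseless recovery exact).
#'
#' @param spec a [decay_model()].
#' @param grid a [time_grid()].
#' @param fit_range a [fit_range()] or `NULL` for the full axis.
#' @return numeric vector of model values, one per bin in the range.
#' @examples
#' g <- time_grid(10, 0.2)
#' eval_model(decay_model(Z = 0, A = 1, tau = 1), g)
#' @export
eval_model <- function(spec, grid, fit_range = NULL) {
  stopifnot(inherits(spec, "flim_model"), inherits(grid, "flim_grid"))
  if (any(spec$tau <= 0) || spec$h <= 0)
    stop("invalid model parameters: 'tau' and 'h' must be positive")
  fit_range <- check_fit_range(fit_range, grid$n_bins)
  t <- bin_centers(grid, fit_range)
  if (spec$kind == "multi_exp") {
    y <- rep.int(spec$Z, length(t))
    for (i in seq_len(spec$n_components))
      y <- y + spec$A[i] * exp(-t / spec$tau[i])
    y
  } else {
    spec$Z + spec$A * exp(-(t / spec$tau)^(1 / spec$h))
  }
}

#' Convolve a model curve with an instrument response function
#'
#' Discrete causal convolution \eqn{c_j = \sum_{k \le j} irf_k\,
#' model_{j-k}}, truncated to the length of the model vector.  The IRF is
#' normalised to unit sum first so that amplitudes keep count units.  The
#' background offset Z must be excluded from the model before convolution
#' and added back afterwards; the fitters do this internally.
#'
#' @param model numeric vector of model values (without offset).
#' @param irf a [flim_irf()] or a non-negative numeric vector; when longer
#'   than `model` only the leading `length(model)` entries are used.
#' @return numeric vector, same length as `model`.
#' @examples
#' convolve_with_irf(c(1, 0.5, 0.25), c(1, 0, 0))  # identity kernel
#' @export
convolve_with_irf <- function(model, irf) {
  if (inherits(irf, "flim_irf")) irf <- irf$counts
  irf <- as.numeric(irf)
  if (anyNA(irf) || any(irf < 0)) stop("IRF values must be non-negative")
  n <- length(model)
  if (length(irf) >= n) irf <- irf[seq_len(n)]
  else irf <- c(irf, numeric(n - length(irf)))
  s <- sum(irf)
  if (s <= 0) stop("IRF is all zero over the model window")
  irf <- irf / s
  out <- numeric(n)
  for (k in which(irf > 0)) {
    # shift-and-add form of the O(n^2) causal sum
    out[k:n] <- out[k:n] + irf[k] * model[seq_len(n - k + 1L)]
  }
  out
}

#' Per-bin variances under a noise model
#'
#' @param noise a [noise_model()]; the `mle` kind has no per-bin variances
#'   (the deviance objective is used instead) and raises an error here.
#' @param data numeric vector of measured counts.
#' @param model optional numeric vector of model values (unused by the
#'   current kinds; accepted for interface symmetry with [objective()]).
#' @return numeric vector of positive variances, one per bin.
#' @examples
#' noise_variance(noise_model("poisson"), c(4, 100))   # 15, 100
#' @export
noise_variance <- function(noise, data, model = NULL) {
  stopifnot(inherits(noise, "flim_noise"))
  data <- as.numeric(data)
  switch(noise$kind,
    constant = rep.int(noise$sigma2, length(data)),
    given = {
      if (length(noise$variances) != length(data))
        stop("'given' variances must match the data length")
      noise$variances
    },
    gaussian = pmax(data, 1),
    poisson = pmax(data, noise$poisson_floor),
    mle = stop("the 'mle' noise model has no per-bin variances; ",
               "it uses the Poisson deviance objective")
  )
}

#' Fit objective: weighted chi-squared or Poisson deviance
#'
#' For the weighted noise kinds the objective is
#' \eqn{\chi^2 = \sum_i (y_i - f_i)^2 / \sigma_i^2}.  For the `mle` kind it
#' is the Poisson deviance
#' \eqn{D = 2\sum_i [f_i - y_i + y_i \ln(y_i/f_i)]}, with the
#' \eqn{y_i = 0} term defined by its limit \eqn{2 f_i}.  Minimising the
#' deviance is equivalent to maximising the Poisson likelihood of the
#' counts.
#'
#' @param data a [decay_curve()] or numeric count vector.
#' @param model numeric vector of model values on the fit range.
#' @param noise a [noise_model()].
#' @param fit_range a [fit_range()] (used when `data` is a curve longer
#'   than `model`).
#' @return single non-negative number.
#' @examples
#' objective(c(4, 16), c(6, 12), noise_model("gaussian"))  # 1 + 1 = 2
#' @export
objective <- function(data, model, noise = noise_model("poisson"),
                      fit_range = NULL) {
  if (inherits(data, "flim_decay")) {
    fit_range <- check_fit_range(fit_range, data$grid$n_bins)
    y <- data$counts[range_idx(fit_range)]
  } else y <- as.numeric(data)
  if (length(y) != length(model))
    stop("data and model must have the same length over the fit range")
  if (noise$kind == "mle") {
    if (any(model <= 0))
      stop("MLE objective requires a strictly positive model curve")
    pos <- y > 0
    dev <- 2 * sum(model - y)
    if (any(pos)) dev <- dev + 2 * sum(y[pos] * log(y[pos] / model[pos]))
    dev
  } else {
    v <- noise_variance(noise, y, model)
    sum((y - model)^2 / v)
  }
}
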