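#' Fit configuration
#'
#' Bundles the options shared by the iterative fitters: fit range, noise
#' model, fixed parameters, box restraints, convergence control and an
#' optional starting model.
#'
#' Parameter names follow the model specification: `"Z"`, `"A1"` ...
#' `"Ak"`, `"tau1"` ... `"tauk"` and (stretched models) `"h"`.
#'
#' @param fit_range a [fit_range()] or `NULL` for the full time axis.
#' @param noise a [noise_model()].
#' @param fixed parameters to hold constant: either a character vector of
#'   names (held at their initial values) or a named numeric vector
#'   (held at the given values, e.g. `c(Z = 0)` for the common
#'   fixed-offset protocol).
#' @param restraints named list of length-2 numeric vectors
#'   `c(lower, upper)`; restrained parameters are projected back into
#'   their box after every accepted step.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @param tol relative objective change declaring convergence.
#' @param initial optional [decay_model()] starting point; by default the
#'   RLD estimate (see [default_initial_estimate()]) is used.
#' @return An object of class `flim_config`.
#' @export
fit_config <- function(fit_range = NULL, noise = noise_model("poisson"),
                       fixed = character(), restraints = list(),
                       max_iter = 100L, tol = 1e-6, initial = NULL) {
  stopifnot(inherits(noise, "flim_noise"))
  if (!is.null(fit_range)) stopifnot(inherits(fit_range, "flim_range"))
  if (!is.null(initial)) stopifnot(inherits(initial, "flim_model"))
  for (nmi in names(restraints)) {
    b <- restraints[[nmi]]
    if (!is.numeric(b) || length(b) != 2 || anyNA(b) || b[1] >= b[2])
      stop("restraint for '", nmi, "' must be c(lower, upper) with lower < upper")
  }
  fixed_values <- NULL
  if (is.numeric(fixed)) {
    if (is.null(names(fixed)) || any(names(fixed) == ""))
      stop("numeric 'fixed' must be a named vector, e.g. c(Z = 0)")
    fixed_values <- fixed
    fixed <- names(fixed)
  }
  structure(list(fit_range = fit_range, noise = noise,
                 fixed = as.character(fixed), fixed_values = fixed_values,
                 restraints = restraints,
                 max_iter = as.integer(max_iter), tol = tol,
                 initial = initial),
            class = "flim_config")
}

param_names <- function(kind, k) {
  if (kind == "multi_exp")
    c("Z", paste0("A", seq_len(k)), paste0("tau", seq_len(k)))
  else c("Z", "A1", "tau1", "h")
}

spec_to_theta <- function(spec) {
  th <- if (spec$kind == "multi_exp") c(spec$Z, spec$A, spec$tau)
        else c(spec$Z, spec$A, spec$tau, spec$h)
  names(th) <- param_names(spec$kind, spec$n_components)
  th
}

theta_to_spec <- function(theta, kind, k) {
  if (kind == "multi_exp")
    decay_model("multi_exp", Z = theta[1], A = theta[1 + seq_len(k)],
                tau = theta[1 + k + seq_len(k)])
  else
    decay_model("stretched_exp", Z = theta[1], A = theta[2], tau = theta[3],
                h = theta[4])
}

# Raw model curve from a parameter vector; NULL when parameters are
# outside the model's domain (so the LM step is rejected, not an error).
theta_curve <- function(theta, kind, k, t, irf_w = NULL) {
  ks <- if (kind == "multi_exp") k else 1L
  taus <- if (kind == "multi_exp") theta[1 + k + seq_len(k)] else theta[3]
  h <- if (kind == "multi_exp") 1 else theta[4]
  if (any(!is.finite(theta)) || any(taus <= 0) || h <= 0) return(NULL)
  Z <- theta[1]
  f <- numeric(length(t))
  if (kind == "multi_exp") {
    for (i in seq_len(k)) f <- f + theta[1 + i] * exp(-t / taus[i])
  } else {
    f <- theta[2] * exp(-(t / taus)^(1 / h))
  }
  if (!is.null(irf_w)) f <- convolve_with_irf(f, irf_w)
  f + Z
}

# Jacobian d model / d theta, n x length(theta); analytic for multi_exp,
# central finite differences (relative step 1e-6) for stretched_exp.
theta_jacobian <- function(theta, kind, k, t, irf_w = NULL) {
  n <- length(t)
  J <- matrix(0, n, length(theta))
  J[, 1] <- 1  # Z enters after convolution
  if (kind == "multi_exp") {
    for (i in seq_len(k)) {
      tau <- theta[1 + k + i]
      e <- exp(-t / tau)
      de <- theta[1 + i] * t * e / tau^2
      if (!is.null(irf_w)) {
        e <- convolve_with_irf(e, irf_w)
        de <- convolve_with_irf(de, irf_w)
      }
      J[, 1 + i] <- e
      J[, 1 + k + i] <- de
    }
  } else {
    for (j in 2:4) {
      step <- 1e-6 * max(abs(theta[j]), 1e-3)
      tp <- theta; tp[j] <- theta[j] + step
      tm <- theta; tm[j] <- theta[j] - step
      fp <- theta_curve(tp, kind, k, t, irf_w)
      fm <- theta_curve(tm, kind, k, t, irf_w)
      if (is.null(fp) || is.null(fm))
        stop("finite-difference step left the parameter domain")
      J[, j] <- (fp - fm) / (2 * step)
    }
  }
  J
}

#' Levenberg-Marquardt decay fitting
#'
#' Nonlinear least-squares (or, with the `mle` noise model,
#' maximum-likelihood) fitting of multi-exponential and
#' stretched-exponential decay models, with optional iterative
#' reconvolution against an instrument response function, parameter fixing
#' and box restraints.
#'
#' The damping factor starts at 1e-3 and is multiplied by 10 on a rejected
#' step and divided by 10 on an accepted step; convergence is declared
#' when the relative objective decrease of an accepted step falls below
#' `config$tol` (or when the damping factor exceeds 1e10).  With an IRF
#' the candidate curve is `convolve_with_irf(model - Z) + Z` at every
#' iteration.  Under the `mle` noise model the Poisson deviance is
#' minimised with the same machinery via its Gauss-Newton approximation
#' (curvature weights `y / f^2`).
#'
#' Standard errors come from the inverse of the curvature (alpha) matrix
#' at the optimum; for the weighted-least-squares noise kinds a copy
#' scaled by the square root of the reduced chi-squared is reported as
#' well (`std_errors`), alongside the unscaled `std_errors_raw`.
#'
#' @param decay a [decay_curve()].
#' @param config a [fit_config()].
#' @param irf optional [flim_irf()] for iterative reconvolution.
#' @param n_components number of exponential components (ignored when
#'   `config$initial` is given).
#' @param kind `"multi_exp"` or `"stretched_exp"`.
#' @return An object of class `flim_fit` with fields `spec` (the fitted
#'   [decay_model()]), `std_errors`, `std_errors_raw`, `reduced_chisq`,
#'   `objective`, `fitted`, `residuals`, `iterations`, `converged`,
#'   `trace` (accepted objective values), `method`, plus the inputs.
#' @examples
#' g <- time_grid(256, 10 / 256)
#' d <- simulate_transient(decay_model(Z = 0, A = 1, tau = 4), g, 10000,
#'                         seed = 42)
#' fit <- fit_lma(d)
#' coef(fit)
#' @export
fit_lma <- function(decay, config = fit_config(), irf = NULL,
                    n_components = 1L, kind = c("multi_exp", "stretched_exp")) {
  stopifnot(inherits(decay, "flim_decay"), inherits(config, "flim_config"))
  kind <- match.arg(kind)
  fr <- check_fit_range(config$fit_range, decay$grid$n_bins)
  y <- decay$counts[range_idx(fr)]
  t <- bin_centers(decay$grid, fr)
  spec0 <- config$initial
  if (is.null(spec0))
    spec0 <- default_initial_estimate(decay, fr, n_components, kind)
  kind <- spec0$kind
  k <- spec0$n_components
  nm <- param_names(kind, k)
  theta <- spec_to_theta(spec0)
  if (!is.null(config$fixed_values)) {
    j <- match(names(config$fixed_values), nm)
    if (anyNA(j)) stop("unknown parameter in 'fixed': ",
                       paste(names(config$fixed_values)[is.na(j)],
                             collapse = ", "))
    theta[j] <- config$fixed_values
  }
  free <- !(nm %in% config$fixed)
  if (!any(free)) stop("at least one parameter must be free")
  if (length(y) < sum(free) + 3L)
    stop("fit range must span at least 3 + number of free parameters bins")
  lower <- rep.int(-Inf, length(theta)); upper <- rep.int(Inf, length(theta))
  for (nmi in names(config$restraints)) {
    j <- match(nmi, nm)
    if (is.na(j)) stop("unknown parameter in restraints: '", nmi, "'")
    lower[j] <- config$restraints[[nmi]][1]
    upper[j] <- config$restraints[[nmi]][2]
  }
  theta <- pmin(pmax(theta, lower), upper)

  irf_w <- NULL
  if (!is.null(irf)) {
    if (inherits(irf, "flim_irf")) {
      if (irf$grid$n_bins != decay$grid$n_bins ||
          abs(irf$grid$bin_width_ns - decay$grid$bin_width_ns) >
            1e-9 * decay$grid$bin_width_ns)
        stop("IRF must share the data's time grid")
      irf_w <- irf$counts[range_idx(fr)]
    } else irf_w <- as.numeric(irf)
    if (sum(irf_w) <= 0) stop("IRF is all zero over the fit range")
    irf_w <- irf_w / sum(irf_w)
  }

  mle <- config$noise$kind == "mle"
  w <- if (!mle) 1 / noise_variance(config$noise, y)
  obj_of <- function(f) {
    if (is.null(f)) return(Inf)
    if (mle) {
      if (any(f <= 0)) return(Inf)
      pos <- y > 0
      2 * sum(f - y) + 2 * sum(y[pos] * log(y[pos] / f[pos]))
    } else sum(w * (y - f)^2)
  }

  f <- theta_curve(theta, kind, k, t, irf_w)
  obj <- obj_of(f)
  if (!is.finite(obj))
    stop("initial parameters are invalid for the chosen objective")
  lambda <- 1e-3
  trace <- obj
  iter <- 0L
  converged <- FALSE
  while (iter < config$max_iter) {
    iter <- iter + 1L
    J <- theta_jacobian(theta, kind, k, t, irf_w)[, free, drop = FALSE]
    cw <- if (mle) y / f^2 else w        # curvature weights
    gw <- if (mle) (y / f - 1) else w * (y - f)
    alpha <- crossprod(J, J * cw)
    beta <- as.vector(crossprod(J, gw))
    dg <- diag(alpha)
    if (any(dg <= 0) || !all(is.finite(alpha)))
      stop("singular curvature matrix: parameter(s) ",
           paste(nm[free][dg <= 0 | !is.finite(dg)], collapse = ", "),
           " have no leverage on the model")
    repeat {
      damped <- alpha + lambda * diag(dg, nrow = length(dg))
      delta <- tryCatch(solve(damped, beta), error = function(e) NULL)
      if (!is.null(delta)) break
      lambda <- lambda * 10
      if (lambda > 1e10)
        stop("singular curvature matrix: damped normal equations unsolvable")
    }
    cand <- theta
    cand[free] <- cand[free] + delta
    cand <- pmin(pmax(cand, lower), upper)
    fc <- theta_curve(cand, kind, k, t, irf_w)
    obj_c <- obj_of(fc)
    if (obj_c <= obj) {  # accepted
      rel <- (obj - obj_c) / max(obj, .Machine$double.eps)
      theta <- cand; f <- fc; obj <- obj_c
      trace <- c(trace, obj)
      lambda <- lambda / 10
      if (rel < config$tol) { converged <- TRUE; break }
    } else {
      lambda <- lambda * 10
      if (lambda > 1e10) { converged <- TRUE; break }
    }
  }

  spec <- theta_to_spec(theta, kind, k)
  n_free <- sum(free)
  dof <- length(y) - n_free
  red <- obj / dof
  # curvature at the optimum, undamped
  J <- theta_jacobian(theta, kind, k, t, irf_w)[, free, drop = FALSE]
  cw <- if (mle) y / f^2 else w
  alpha <- crossprod(J, J * cw)
  se_raw <- tryCatch(sqrt(diag(solve(alpha))), error = function(e) {
    warning("curvature matrix singular at the optimum; no error estimates")
    rep.int(NA_real_, n_free)
  })
  names(se_raw) <- nm[free]
  se <- if (mle) se_raw else se_raw * sqrt(max(red, 0))
  structure(list(spec = spec, method = "lma",
                 std_errors = se, std_errors_raw = se_raw,
                 objective = obj, reduced_chisq = red, dof = dof,
                 fitted = f, residuals = y - f,
                 iterations = iter, converged = converged, trace = trace,
                 alpha = alpha, data = decay, fit_range = fr,
                 noise = config$noise, irf = !is.null(irf_w)),
            class = "flim_fit")
}

#' Parameter errors from the curvature (alpha) matrix
#'
#' Standard errors are the square roots of the diagonal of the inverse
#' curvature matrix, optionally scaled by the square root of the reduced
#' chi-squared (the convention for weighted-least-squares fits).
#'
#' @param alpha symmetric positive-definite curvature matrix of the free
#'   parameters at the optimum.
#' @param reduced_chisq reduced chi-squared used as scale factor
#'   (default 1 leaves the errors unscaled).
#' @return numeric vector of standard errors.
#' @examples
#' estimate_errors(diag(c(4, 25)))  # 0.5, 0.2
#' @export
estimate_errors <- function(alpha, reduced_chisq = 1) {
  inv <- tryCatch(solve(alpha),
                  error = function(e) stop("alpha matrix is not invertible"))
  d <- diag(inv)
  if (any(d < 0)) stop("alpha matrix is not positive definite")
  sqrt(d * reduced_chisq)
}

#' Default initial estimate for iterative fitting
#'
#' Uses the RLD closed form where it succeeds; a multi-component request
#' splits the RLD lifetime geometrically (`tau/2, 2*tau`, ...) and divides
#' the amplitude equally.  When RLD fails (flat or rising transients) a
#' heuristic from the curve extrema and a lifetime of a quarter of the
#' range duration is returned, so an initial estimate always exists.
#'
#' @param decay a [decay_curve()].
#' @param fit_range a [fit_range()] or `NULL`.
#' @param n_components number of exponential components requested.
#' @param kind model kind; for `"stretched_exp"` the stretch is started
#'   at `h = 1`.
#' @return a [decay_model()].
#' @export
default_initial_estimate <- function(decay, fit_range = NULL,
                                     n_components = 1L,
                                     kind = c("multi_exp", "stretched_exp")) {
  kind <- match.arg(kind)
  k <- as.integer(n_components)
  if (kind == "stretched_exp" && k != 1L)
    stop("stretched_exp models have exactly one component")
  fr <- check_fit_range(fit_range, decay$grid$n_bins)
  est <- tryCatch(rld_core(decay$counts[range_idx(fr)],
                           decay$grid$bin_width_ns),
                  error = function(e) NULL)
  if (is.null(est)) {
    y <- decay$counts[range_idx(fr)]
    dur <- (fr$end_bin - fr$start_bin) * decay$grid$bin_width_ns
    est <- list(Z = min(y), A = max(max(y) - min(y), 1), tau = dur / 4)
  }
  if (kind == "stretched_exp")
    return(decay_model("stretched_exp", Z = est$Z, A = est$A, tau = est$tau,
                       h = 1))
  if (k == 1L)
    return(decay_model(Z = est$Z, A = est$A, tau = est$tau))
  taus <- est$tau * 2^(2 * seq_len(k) - (k + 1))
  decay_model(Z = est$Z, A = rep.int(est$A / k, k), tau = taus)
}

# Shared closing step for non-iterative fitters (RLD, Bayes): evaluate the
# fitted curve, residuals and reduced chi-squared for a known spec.
finish_fit <- function(decay, fr, spec, noise, method, iterations, converged,
                       std_errors = NULL, n_free = 3L, extra = list()) {
  y <- decay$counts[range_idx(fr)]
  f <- eval_model(spec, decay$grid, fr)
  chisq_noise <- if (noise$kind == "mle") noise_model("poisson") else noise
  obj <- sum((y - f)^2 / noise_variance(chisq_noise, y))
  dof <- length(y) - n_free
  out <- c(list(spec = spec, method = method,
                std_errors = std_errors, std_errors_raw = std_errors,
                objective = obj, reduced_chisq = obj / dof, dof = dof,
                fitted = f, residuals = y - f,
                iterations = iterations, converged = converged,
                trace = obj, alpha = NULL, data = decay, fit_range = fr,
                noise = noise, irf = FALSE),
           extra)
  class(out) <- c(if (method == "bayes") "flim_bayes", "flim_fit")
  out
}
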