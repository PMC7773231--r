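#' Linear amplitude solve for fixed lifetimes
#'
#' With the lifetimes held fixed, the offset and component amplitudes
#' enter the multi-exponential model linearly, so the optimal
#' `(Z, A_1, ..., A_k)` for one transient is the exact weighted
#' linear-least-squares solution against the basis
#' `{1, exp(-t/tau_1), ..., exp(-t/tau_k)}` (normal equations).
#'
#' @param decay a [decay_curve()].
#' @param tau numeric vector of fixed positive lifetimes (distinct).
#' @param noise a [noise_model()] supplying the weights (the `mle` kind is
#'   not supported here).
#' @param fit_range a [fit_range()] or `NULL`.
#' @return list with `Z`, `A` (length `k`), and the weighted residual
#'   `chisq`.
#' @export
solve_linear_amplitudes <- function(decay, tau, noise = noise_model("poisson"),
                                    fit_range = NULL) {
  stopifnot(inherits(decay, "flim_decay"))
  if (any(tau <= 0)) stop("lifetimes must be positive")
  if (anyDuplicated(tau)) stop("duplicate lifetimes give a collinear basis")
  if (noise$kind == "mle")
    stop("linear amplitude solves require a weighted noise model")
  fr <- check_fit_range(fit_range, decay$grid$n_bins)
  y <- decay$counts[range_idx(fr)]
  t <- bin_centers(decay$grid, fr)
  X <- cbind(1, exp(-outer(t, tau, "/")))
  w <- 1 / noise_variance(noise, y)
  M <- crossprod(X, X * w)
  rhs <- crossprod(X, w * y)
  a <- tryCatch(solve(M, rhs), error = function(e)
    stop("collinear basis: lifetimes too close for a stable solve"))
  f <- as.vector(X %*% a)
  list(Z = a[1], A = as.vector(a[-1]), chisq = sum(w * (y - f)^2))
}

# Batch linear solves for a matrix of transients (bins x pixels) sharing
# one basis but with per-pixel weights.  Returns coefficient matrix
# (k+1) x P, residual matrix, chisq vector and a validity flag.
solve_linear_batch <- function(Y, W, X) {
  p <- ncol(X); P <- ncol(Y)
  XWY <- crossprod(X, W * Y)              # p x P
  # per-pixel normal matrices via columnwise sums of X_a X_b w
  cross <- array(0, dim = c(p, p, P))
  for (a in seq_len(p)) for (b in a:p) {
    v <- .colSums(W * (X[, a] * X[, b]), nrow(Y), P)
    cross[a, b, ] <- v
    cross[b, a, ] <- v
  }
  coef <- matrix(NA_real_, p, P)
  ok <- logical(P)
  for (j in seq_len(P)) {
    sol <- tryCatch(solve(cross[, , j], XWY[, j]), error = function(e) NULL)
    if (!is.null(sol)) { coef[, j] <- sol; ok[j] <- TRUE }
  }
  Fhat <- X %*% ifelse(is.na(coef), 0, coef)
  R <- Y - Fhat
  chisq <- .colSums(W * R^2, nrow(Y), P)
  chisq[!ok] <- NA_real_
  list(coef = coef, resid = R, chisq = chisq, valid = ok)
}

#' Global analysis: image-wide shared lifetimes
#'
#' Fits all pixels of an image simultaneously with a multi-exponential
#' model in which the lifetimes are shared across pixels while the offset
#' and amplitudes remain local, via variable projection: an outer
#' Levenberg-Marquardt loop over the shared lifetimes minimises the total
#' weighted chi-squared, and at each candidate lifetime vector the
#' per-pixel `(Z, A_i)` are profiled out exactly with
#' [solve_linear_amplitudes()].  The outer loop is initialised from a
#' Levenberg-Marquardt fit of the image-summed transient.
#'
#' @param image a [flim_image()].
#' @param n_components number of shared lifetimes.
#' @param config a [fit_config()] (fit range, weighted noise model,
#'   `max_iter`, `tol`; `initial` may supply starting lifetimes).
#' @param intensity_threshold pixels whose in-range photon sum is below
#'   this value are excluded from the fit and returned as NaN.
#' @return An object of class `flim_global` with fields `global_tau`
#'   (sorted ascending), `maps` (per-pixel `Z`, `A1`..`Ak`,
#'   `reduced_chisq` matrices), `total_chisq`, `iterations`, `converged`,
#'   `trace`, `mask`.
#' @examples
#' sim <- simulate_twocomp_image(size = c(16, 16), photons_per_pixel = 2000,
#'                               seed = 1)
#' \donttest{fit_global(sim$image)$global_tau}
#' @export
fit_global <- function(image, n_components = 2L, config = fit_config(),
                       intensity_threshold = 0) {
  stopifnot(inherits(image, "flim_image"))
  if (config$noise$kind == "mle")
    stop("global analysis requires a weighted noise model")
  k <- as.integer(n_components)
  fr <- check_fit_range(config$fit_range, image$grid$n_bins)
  idx <- range_idx(fr)
  d <- dim(image$counts)
  npix <- d[2] * d[3]
  Y_all <- matrix(image$counts[idx, , ], nrow = length(idx))
  intensity <- .colSums(Y_all, length(idx), npix)
  keep <- intensity >= intensity_threshold
  if (sum(keep) < 2L)
    stop("global analysis needs at least 2 pixels above the threshold")
  Y <- Y_all[, keep, drop = FALSE]
  t <- bin_centers(image$grid, fr)
  n <- length(t); P <- ncol(Y)
  W <- 1 / matrix(noise_variance(config$noise, Y), n, P)

  # initial shared lifetimes from the image-summed transient
  tau <- if (!is.null(config$initial)) config$initial$tau else {
    summed <- decay_curve(rowSums(matrix(image$counts, nrow = d[1])),
                          image$grid)
    init_fit <- tryCatch(
      fit_lma(summed,
              fit_config(fit_range = fr, noise = config$noise,
                         max_iter = config$max_iter, tol = config$tol),
              n_components = k),
      error = function(e) NULL)
    if (is.null(init_fit)) default_initial_estimate(summed, fr, k)$tau
    else init_fit$spec$tau
  }
  if (length(tau) != k) stop("initial lifetimes must have length n_components")

  inner <- function(tau) {
    X <- cbind(1, exp(-outer(t, tau, "/")))
    solve_linear_batch(Y, W, X)
  }
  total_obj <- function(sol) sum(sol$chisq[sol$valid])

  sol <- inner(tau)
  if (mean(sol$valid) < 0.5)
    stop("linear amplitude solve failed on more than half of the pixels")
  obj <- total_obj(sol)
  lambda <- 1e-3
  trace <- obj
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    # gradient/curvature of the profiled objective (exact at the inner
    # optimum by the envelope property of least squares)
    dq <- lapply(tau, function(tk) t * exp(-t / tk) / tk^2)  # n-vectors
    Amat <- sol$coef[-1, , drop = FALSE]                     # k x P
    alpha <- matrix(0, k, k); beta <- numeric(k)
    WR <- W * sol$resid
    for (a in seq_len(k)) {
      beta[a] <- sum(.colSums(WR * dq[[a]], n, P)[sol$valid] *
                       Amat[a, sol$valid])
      for (b in a:k) {
        g <- .colSums(W * (dq[[a]] * dq[[b]]), n, P)
        alpha[a, b] <- alpha[b, a] <-
          sum(g[sol$valid] * Amat[a, sol$valid] * Amat[b, sol$valid])
      }
    }
    dg <- diag(alpha)
    if (any(dg <= 0) || !all(is.finite(alpha)))
      stop("singular curvature matrix in the global lifetime update")
    step_ok <- FALSE
    repeat {
      damped <- alpha + lambda * diag(dg, nrow = k)
      delta <- tryCatch(solve(damped, beta), error = function(e) NULL)
      cand <- tau + if (is.null(delta)) NA else delta
      if (!is.null(delta) && all(cand > 0) && !anyDuplicated(cand)) {
        sol_c <- inner(cand)
        obj_c <- if (mean(sol_c$valid) < 0.5) Inf else total_obj(sol_c)
        if (obj_c <= obj) {
          rel <- (obj - obj_c) / max(obj, .Machine$double.eps)
          tau <- cand; sol <- sol_c; obj <- obj_c
          trace <- c(trace, obj)
          lambda <- lambda / 10
          step_ok <- TRUE
          if (rel < config$tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e10) { converged <- TRUE; break }
    }
    if (converged || !step_ok) break
  }

  ord <- order(tau)
  tau <- tau[ord]
  coef_all <- matrix(NA_real_, k + 1L, npix)
  coef_all[, keep] <- sol$coef[c(1L, 1L + ord), , drop = FALSE]
  chisq_all <- rep.int(NA_real_, npix)
  chisq_all[keep] <- sol$chisq
  as_map <- function(v) matrix(v, d[2], d[3])
  maps <- c(list(Z = as_map(coef_all[1, ])),
            stats::setNames(lapply(seq_len(k), function(i)
              as_map(coef_all[1 + i, ])), paste0("A", seq_len(k))),
            list(reduced_chisq = as_map(chisq_all / (n - (k + 1L)))))
  structure(list(global_tau = tau, maps = maps,
                 total_chisq = obj, iterations = iter,
                 converged = converged, trace = trace,
                 mask = as_map(keep), intensity = as_map(intensity),
                 n_components = k, fit_range = fr, noise = config$noise),
            class = "flim_global")
}

#' @export
print.flim_global <- function(x, digits = 4, ...) {
  cat(sprintf("<flim_global> %d-component global fit of %d pixels\n",
              x$n_components, sum(x$mask)))
  cat("  shared lifetimes (ns):",
      paste(format(x$global_tau, digits = digits), collapse = ", "), "\n")
  cat(sprintf("  total chi-squared %.6g after %d outer iterations%s\n",
              x$total_chisq, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
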