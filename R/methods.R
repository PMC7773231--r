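# S3 methods for single-transient fit objects.

#' @export
print.flim_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<flim_fit> method '%s'%s\n", x$method,
              if (isTRUE(x$irf)) " (IRF reconvolution)" else ""))
  print(x$spec, digits = digits)
  cat(sprintf("  reduced chi-squared: %s  (%d d.o.f.)\n",
              format(x$reduced_chisq, digits = digits), x$dof))
  if (!isTRUE(x$converged)) cat("  WARNING: did not converge\n")
  invisible(x)
}

#' @export
summary.flim_fit <- function(object, ...) {
  co <- coef(object)
  se <- object$std_errors
  tab <- cbind(Estimate = co,
               `Std. Error` = if (is.null(se)) rep(NA_real_, length(co))
                              else se[match(names(co), names(se))])
  out <- list(method = object$method, table = tab,
              reduced_chisq = object$reduced_chisq, dof = object$dof,
              iterations = object$iterations, converged = object$converged,
              irf = object$irf)
  class(out) <- "summary.flim_fit"
  out
}

#' @export
print.summary.flim_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Decay fit by '%s'%s\n", x$method,
              if (isTRUE(x$irf)) " with IRF reconvolution" else ""))
  stats::printCoefmat(x$table, digits = digits, na.print = "-")
  cat(sprintf("Reduced chi-squared: %s on %d degrees of freedom\n",
              format(x$reduced_chisq, digits = digits), x$dof))
  if (is.finite(x$iterations) && !is.na(x$iterations))
    cat(sprintf("Iterations: %d (%s)\n", x$iterations,
                if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.flim_fit <- function(object, ...) spec_to_theta(object$spec)

#' @export
fitted.flim_fit <- function(object, ...) object$fitted

#' @export
residuals.flim_fit <- function(object, ...) object$residuals

#' @export
deviance.flim_fit <- function(object, ...) object$objective

#' Predict a fitted decay model at arbitrary times
#'
#' @param object a `flim_fit`.
#' @param times numeric times (ns, measured from the fit-range start);
#'   default the fitted bin centres.
#' @param ... unused.
#' @return numeric vector of model values (IRF-free model curve).
#' @export
predict.flim_fit <- function(object, times = NULL, ...) {
  if (is.null(times))
    return(object$fitted)
  s <- object$spec
  if (s$kind == "multi_exp") {
    y <- rep.int(s$Z, length(times))
    for (i in seq_len(s$n_components))
      y <- y + s$A[i] * exp(-times / s$tau[i])
    y
  } else s$Z + s$A * exp(-(times / s$tau)^(1 / s$h))
}

#' Simulate Poisson replicates from a fitted model
#'
#' Draws `nsim` Poisson realisations of the fitted curve over the fit
#' range (parametric bootstrap of the photon statistics).
#'
#' @param object a `flim_fit`.
#' @param nsim number of replicate curves.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return numeric matrix, one column per replicate.
#' @export
simulate.flim_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- pmax(object$fitted, 0)
  with_seed(seed, matrix(stats::rpois(length(mu) * nsim, mu),
                         ncol = nsim))
}

#' @export
plot.flim_fit <- function(x, log = "", ...) {
  fr <- x$fit_range
  t <- bin_centers(x$data$grid, fr)
  y <- x$data$counts[range_idx(fr)]
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(t, y, pch = 16, cex = 0.4, log = log,
                 xlab = "time from fit start (ns)", ylab = "counts", ...)
  graphics::lines(t, x$fitted, col = 2, lwd = 2)
  graphics::plot(t, x$residuals, type = "h",
                 xlab = "time from fit start (ns)", ylab = "residual")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
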