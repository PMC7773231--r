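# Levenberg-Marquardt fitting: optimisation, noise models, IRF
# reconvolution, restraints and error estimates.

test_that("a fit started at the global minimum stays there", {
  g <- std_grid(128)
  truth <- decay_model(Z = 3, A = 200, tau = 2.2)
  d <- decay_curve(eval_model(truth, g), g)
  fit <- fit_lma(d, fit_config(initial = truth))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(3, 200, 2.2), tolerance = 1e-9)
  expect_lt(fit$reduced_chisq, 1e-12)
})

test_that("two-free-parameter fit agrees with an exhaustive grid search", {
  g <- std_grid(64)
  set.seed(13)
  d <- simulate_transient(decay_model(Z = 0, A = 1, tau = 2), g, 3000)
  fit <- fit_lma(d, fit_config(fixed = c(Z = 0), tol = 1e-12))
  co <- coef(fit)

  # brute-force 1000 x 1000 grid over (A, tau), direct chi-squared
  y <- d$counts
  t <- bin_centers(g)
  v <- pmax(y, 15)
  A_grid <- seq(0.7 * co[["A1"]], 1.3 * co[["A1"]], length.out = 1000)
  tau_grid <- seq(0.8 * co[["tau1"]], 1.2 * co[["tau1"]], length.out = 1000)
  best <- c(Inf, NA, NA)
  for (ti in seq_along(tau_grid)) {
    e <- exp(-t / tau_grid[ti])
    chis <- colSums((y - outer(e, A_grid))^2 / v)
    j <- which.min(chis)
    if (chis[j] < best[1]) best <- c(chis[j], A_grid[j], tau_grid[ti])
  }
  cell_A <- diff(A_grid[1:2]); cell_tau <- diff(tau_grid[1:2])
  expect_lt(abs(co[["A1"]] - best[2]), cell_A)
  expect_lt(abs(co[["tau1"]] - best[3]), cell_tau)
  expect_lte(fit$objective, best[1] + 1e-9)
})

test_that("the objective never increases across accepted iterations", {
  g <- std_grid()
  set.seed(17)
  for (i in 1:5) {
    d <- simulate_transient(decay_model(Z = 2, A = 1, tau = runif(1, 0.5, 5)),
                            g, 4000)
    fit <- suppressWarnings(fit_lma(d))
    expect_true(all(diff(fit$trace) <= 1e-9 * abs(fit$trace[-1] + 1)))
  }
})

test_that("constant-variance fits are invariant to sigma2 up to chi-squared scale", {
  g <- std_grid(128)
  d <- simulate_transient(decay_model(Z = 1, A = 1, tau = 3), g, 5000,
                          seed = 23)
  f1 <- fit_lma(d, fit_config(noise = noise_model("constant", sigma2 = 1)))
  f4 <- fit_lma(d, fit_config(noise = noise_model("constant", sigma2 = 4)))
  expect_equal(coef(f1), coef(f4), tolerance = 1e-6)
  expect_equal(f1$objective / 4, f4$objective, tolerance = 1e-6)
})

test_that("MLE and Gaussian weighting agree on high-count data", {
  g <- std_grid()
  set.seed(31)
  for (i in 1:5) {
    tau <- runif(1, 1, 4)
    d <- simulate_transient(decay_model(Z = 0, A = 1, tau = tau), g, 50000)
    t_mle <- coef(fit_lma(d, fit_config(noise = noise_model("mle"),
                                        fixed = c(Z = 0))))[["tau1"]]
    t_gau <- coef(fit_lma(d, fit_config(noise = noise_model("gaussian"),
                                        fixed = c(Z = 0))))[["tau1"]]
    expect_equal(t_mle, t_gau, tolerance = 0.02)
  }
})

test_that("a delta-function IRF changes nothing", {
  g <- std_grid(128)
  d <- simulate_transient(decay_model(Z = 2, A = 1, tau = 2.5), g, 8000,
                          seed = 37)
  delta <- flim_irf(c(1, numeric(127)), g)
  f0 <- fit_lma(d)
  f1 <- fit_lma(d, irf = delta)
  expect_equal(coef(f0), coef(f1), tolerance = 1e-9)
  expect_true(f1$irf)
})

test_that("iterative reconvolution recovers the lifetime under an IRF", {
  g <- std_grid()
  irf <- gaussian_irf(g)
  truth <- decay_model(Z = 0, A = 1, tau = 3)
  mu <- flimfit:::expected_transient(truth, g, 10000, irf = irf)
  d <- decay_curve(mu, g)
  init <- decay_model(Z = 0, A = max(mu), tau = 2)
  fit <- fit_lma(d, fit_config(initial = init, fixed = c(Z = 0),
                               tol = 1e-12, max_iter = 200), irf = irf)
  expect_equal(unname(coef(fit)["tau1"]), 3, tolerance = 1e-6)

  # without reconvolution the apparent lifetime is biased by the prompt
  naive <- fit_lma(d, fit_config(fixed = c(Z = 0)))
  expect_gt(abs(coef(naive)[["tau1"]] - 3), 0.02)
})

test_that("box restraints clamp parameters and fixing at truth helps", {
  g <- std_grid(128)
  d <- simulate_transient(decay_model(Z = 0, A = 1, tau = 2), g, 5000,
                          seed = 41)
  fit <- fit_lma(d, fit_config(restraints = list(tau1 = c(0.5, 1.5)),
                               fixed = c(Z = 0)))
  expect_equal(coef(fit)[["tau1"]], 1.5)

  # fixing Z at its true value never worsens the lifetime RMSE
  set.seed(43)
  errs <- replicate(60, {
    d <- simulate_transient(decay_model(Z = 0, A = 1, tau = 4), g, 3000)
    c(free = coef(fit_lma(d))[["tau1"]],
      fixed = coef(fit_lma(d, fit_config(fixed = c(Z = 0))))[["tau1"]])
  })
  rmse <- sqrt(rowMeans((errs - 4)^2))
  expect_lte(rmse[["fixed"]], rmse[["free"]])
})

test_that("alpha-matrix error estimates are exact and calibrated", {
  expect_equal(estimate_errors(diag(2)), c(1, 1))
  expect_equal(estimate_errors(diag(c(4, 25))), c(0.5, 0.2))
  expect_equal(estimate_errors(diag(c(4, 25)), reduced_chisq = 4),
               c(1, 0.4))
  expect_error(estimate_errors(matrix(0, 2, 2)), "invertible")

  # simulation coverage: truth within +/- 1 sigma in ~68% of replicates
  # (under the unbiased maximum-likelihood objective; the weighted
  # chi-squared kinds carry a small low-count bias that shifts coverage
  # even though the error magnitudes are calibrated)
  g <- std_grid(128)
  set.seed(47)
  hits <- replicate(1000, {
    d <- simulate_transient(decay_model(Z = 0, A = 1, tau = 2), g, 5000)
    fit <- fit_lma(d, fit_config(noise = noise_model("mle"),
                                 fixed = c(Z = 0)))
    abs(coef(fit)[["tau1"]] - 2) <= fit$std_errors[["tau1"]]
  })
  expect_gt(mean(hits), 0.64)
  expect_lt(mean(hits), 0.72)

  # and the reported error magnitude matches the ensemble spread
  set.seed(48)
  res <- replicate(300, {
    d <- simulate_transient(decay_model(Z = 0, A = 1, tau = 2), g, 5000)
    fit <- fit_lma(d, fit_config(fixed = c(Z = 0)))
    c(coef(fit)[["tau1"]], fit$std_errors[["tau1"]])
  })
  expect_equal(sd(res[1, ]), mean(res[2, ]), tolerance = 0.15)
})

test_that("stretched-exponential fitting works and reduces at h = 1", {
  g <- std_grid(128)
  truth <- decay_model("stretched_exp", Z = 0, A = 300, tau = 1.5, h = 1.6)
  d <- decay_curve(eval_model(truth, g), g)
  init <- decay_model("stretched_exp", Z = 0, A = 250, tau = 2, h = 1)
  fit <- fit_lma(d, fit_config(initial = init, fixed = c(Z = 0),
                               tol = 1e-14, max_iter = 500),
                 kind = "stretched_exp")
  expect_equal(coef(fit)[["tau1"]], 1.5, tolerance = 1e-4)
  expect_equal(coef(fit)[["h"]], 1.6, tolerance = 1e-4)

  # h fixed at 1 reproduces the plain mono-exponential fit
  d2 <- simulate_transient(decay_model(Z = 0, A = 1, tau = 2), g, 5000,
                           seed = 53)
  fs <- fit_lma(d2, fit_config(fixed = c(Z = 0, h = 1)),
                kind = "stretched_exp")
  fm <- fit_lma(d2, fit_config(fixed = c(Z = 0)))
  expect_equal(fs$spec$tau, fm$spec$tau, tolerance = 1e-5)
})

test_that("default initial estimates follow the documented rules", {
  g <- std_grid(240)
  d <- noiseless_decay(Z = 5, A = 120, tau = 1.8, g)
  init <- default_initial_estimate(d)
  rld <- fit_rld(d)$spec
  expect_equal(init$tau, rld$tau, tolerance = 1e-12)
  expect_equal(init$A, rld$A, tolerance = 1e-12)

  init2 <- default_initial_estimate(d, n_components = 2)
  expect_equal(init2$tau, c(rld$tau / 2, 2 * rld$tau), tolerance = 1e-12)
  expect_equal(init2$A, rep(rld$A / 2, 2), tolerance = 1e-12)

  flat <- decay_curve(rep(9, 240), g)
  init3 <- default_initial_estimate(flat)
  expect_gt(init3$tau, 0)
  expect_gt(init3$A, 0)
})

test_that("weighted fits agree with an independent nonlinear least-squares solver", {
  skip_if_not_installed("minpack.lm")
  g <- std_grid(128)
  d <- simulate_transient(decay_model(Z = 0, A = 1, tau = 2.7), g, 8000,
                          seed = 59)
  fit <- fit_lma(d, fit_config(noise = noise_model("poisson"), tol = 1e-12))
  y <- d$counts; t <- bin_centers(g); w <- 1 / pmax(y, 15)
  ref <- minpack.lm::nlsLM(y ~ Z + A * exp(-t / tau),
                           start = list(Z = 1, A = max(y), tau = 2),
                           weights = w,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  expect_equal(coef(fit)[["tau1"]], coef(ref)[["tau"]], tolerance = 1e-4)
  expect_equal(coef(fit)[["A1"]], coef(ref)[["A"]], tolerance = 1e-4)
})

test_that("degenerate configurations raise informative errors", {
  g <- std_grid(16)
  d <- simulate_transient(decay_model(Z = 0, A = 1, tau = 2), g, 500,
                          seed = 61)
  expect_error(fit_lma(d, fit_config(fixed = c("Z", "A1", "tau1"))),
               "free")
  # amplitude pinned at zero leaves tau without leverage
  init <- decay_model(Z = 0, A = 0, tau = 1)
  expect_error(fit_lma(d, fit_config(initial = init, fixed = c("Z", "A1"))),
               "singular|leverage")
})
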