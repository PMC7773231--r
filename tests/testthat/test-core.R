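# Decay models, IRF convolution, noise variances and fit objectives.

test_that("model evaluation matches closed forms and degenerate cases", {
  # bin centred at t = 1 ns: 2 ns bins starting at 0
  g <- time_grid(3, 2)
  y <- eval_model(decay_model(Z = 0, A = 1, tau = 1), g)
  expect_equal(y[1], exp(-1), tolerance = 1e-12)
  expect_equal(y, exp(-c(1, 3, 5)), tolerance = 1e-12)

  # amplitude-zero model is the flat offset
  expect_equal(eval_model(decay_model(Z = 5, A = 0, tau = 2), g),
               rep(5, 3))

  # stretched exponential with h = 1 reduces to the mono-exponential
  g2 <- std_grid(64)
  me <- eval_model(decay_model(Z = 2, A = 30, tau = 1.7), g2)
  se <- eval_model(decay_model("stretched_exp", Z = 2, A = 30, tau = 1.7,
                               h = 1), g2)
  expect_equal(se, me, tolerance = 1e-12)

  # time restarts at the fit-range start
  fr <- fit_range(10, 20)
  expect_equal(eval_model(decay_model(Z = 0, A = 1, tau = 1), g2, fr),
               eval_model(decay_model(Z = 0, A = 1, tau = 1),
                          time_grid(10, g2$bin_width_ns)))

  expect_error(decay_model(Z = 0, A = 1, tau = -1), "positive")
  expect_error(decay_model("stretched_exp", Z = 0, A = 1, tau = 1, h = 0),
               "positive")
})

test_that("multi-exponential curves are non-increasing for non-negative parameters", {
  g <- std_grid(64)
  set.seed(1)
  for (i in 1:20) {
    k <- sample(1:3, 1)
    spec <- decay_model(Z = runif(1, 0, 10), A = runif(k, 0, 100),
                        tau = runif(k, 0.1, 8))
    y <- eval_model(spec, g)
    expect_true(all(diff(y) <= 1e-12))
  }
})

test_that("IRF convolution is causal, matches the double-loop sum, and is linear", {
  # identity kernel
  m <- c(5, 3, 2, 1)
  expect_equal(convolve_with_irf(m, c(1, 0, 0, 0)), m)
  # zero model
  expect_equal(convolve_with_irf(numeric(8), c(runif(8))), numeric(8))

  # brute-force O(n^2) oracle
  set.seed(7)
  model <- runif(16); irf <- runif(16)
  irf_n <- irf / sum(irf)
  oracle <- numeric(16)
  for (j in 1:16) for (k in 1:j)
    oracle[j] <- oracle[j] + irf_n[k] * model[j - k + 1]
  expect_equal(convolve_with_irf(model, irf), oracle, tolerance = 1e-12)

  # linearity on random 32-bin inputs
  for (i in 1:5) {
    m1 <- runif(32); m2 <- runif(32); irf <- runif(32)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    expect_equal(convolve_with_irf(a * m1 + b * m2, irf),
                 a * convolve_with_irf(m1, irf) +
                   b * convolve_with_irf(m2, irf),
                 tolerance = 1e-10)
  }

  expect_error(convolve_with_irf(m, c(0, 0, 0, 0)), "zero")
})

test_that("noise variances follow each model kind", {
  pois <- noise_model("poisson")
  expect_identical(noise_variance(pois, c(4, 100)), c(15, 100))
  expect_identical(noise_variance(pois, c(0, 14.9, 15, 16)),
                   c(15, 15, 15, 16))
  expect_equal(noise_variance(noise_model("constant", sigma2 = 2),
                              c(1, 50, 9)), rep(2, 3))
  expect_equal(noise_variance(noise_model("gaussian"), c(0, 0.5, 7)),
               c(1, 1, 7))
  expect_equal(noise_variance(noise_model("given", variances = c(2, 3)),
                              c(9, 9)), c(2, 3))
  expect_error(noise_model("given", variances = c(1, -1)), "positive")
  expect_error(noise_variance(noise_model("mle"), c(1, 2)), "deviance")
})

test_that("objective computes weighted chi-squared and Poisson deviance", {
  for (kind in c("gaussian", "poisson", "constant", "mle"))
    expect_equal(objective(c(10, 20, 30), c(10, 20, 30),
                           noise_model(kind)), 0)
  # hand-computed chi-squared with var_i = y_i
  expect_equal(objective(c(4, 16), c(6, 12), noise_model("gaussian")), 2)
  # hand-computed deviance
  expect_equal(objective(4, 6, noise_model("mle")),
               2 * (6 - 4 + 4 * log(4 / 6)), tolerance = 1e-12)
  expect_equal(objective(4, 6, noise_model("mle")), 0.7562792,
               tolerance = 1e-6)
  # empty bins contribute 2 f
  expect_equal(objective(c(0, 0), c(3, 1.5), noise_model("mle")), 9)
  expect_error(objective(c(1, 1), c(1, -1), noise_model("mle")), "positive")
})

test_that("Poisson deviance is non-negative, zero only at the data", {
  set.seed(11)
  mle <- noise_model("mle")
  for (i in 1:50) {
    y <- rpois(16, 20) + 1  # strictly positive counts
    f <- y * exp(runif(16, -0.3, 0.3))
    d <- objective(y, f, mle)
    expect_gte(d, 0)
    if (max(abs(f - y)) > 1e-8) expect_gt(d, 0)
  }
  y <- rpois(16, 20) + 1
  expect_equal(objective(y, as.numeric(y), mle), 0)
})

test_that("weighted objectives ignore bins outside the fit range", {
  g <- std_grid(32)
  set.seed(3)
  y <- rpois(32, 40)
  d <- decay_curve(y, g)
  fr <- fit_range(0, 20)
  f <- eval_model(decay_model(Z = 5, A = 60, tau = 2), g, fr)
  for (kind in c("gaussian", "poisson")) {
    o1 <- objective(d, f, noise_model(kind), fr)
    # perturb the bins beyond the range
    y2 <- y; y2[21:32] <- y2[21:32] + 500
    o2 <- objective(decay_curve(y2, g), f, noise_model(kind), fr)
    expect_identical(o1, o2)
  }
})
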