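# Image-level operations: binning, thresholding, per-pixel maps, mean
# lifetime, FRET.

test_that("spatial binning sums neighbourhoods with zero padding", {
  g <- std_grid(16)
  set.seed(127)
  counts <- array(as.double(rpois(16 * 8 * 8, 20)), dim = c(16, 8, 8))
  img <- flim_image(counts, g)
  expect_identical(bin_image(img, 1)$counts, counts)

  b_fft <- bin_image(img, 3, method = "fft")
  b_dir <- bin_image(img, 3, method = "direct")

  # brute-force nested-loop oracle
  oracle <- array(0, dim = c(16, 8, 8))
  for (y in 1:8) for (x in 1:8) for (dy in -1:1) for (dx in -1:1) {
    yy <- y + dy; xx <- x + dx
    if (yy >= 1 && yy <= 8 && xx >= 1 && xx <= 8)
      oracle[, y, x] <- oracle[, y, x] + counts[, yy, xx]
  }
  expect_equal(b_dir$counts, oracle, tolerance = 1e-12)
  expect_equal(b_fft$counts, oracle, tolerance = 1e-6 * max(oracle))

  # interior pixels conserve photons: a uniform image triples twice
  uni <- flim_image(array(5, dim = c(4, 6, 6)), time_grid(4, 1))
  bu <- bin_image(uni, 3, method = "direct")
  expect_equal(bu$counts[, 3, 3], rep(45, 4))
  expect_error(bin_image(img, 2), "odd")
})

test_that("ROI cropping follows half-open 0-based pixel ranges", {
  g <- std_grid(8)
  counts <- array(seq_len(8 * 6 * 5), dim = c(8, 6, 5))
  img <- flim_image(counts, g)
  cr <- crop_image(img, y0 = 1, y1 = 4, x0 = 0, x1 = 2)
  expect_equal(dim(cr$counts), c(8L, 3L, 2L))
  expect_equal(cr$counts[, 1, 1], counts[, 2, 1])
  mask <- matrix(TRUE, 3, 2); mask[2, 2] <- FALSE
  crm <- crop_image(img, y0 = 1, y1 = 4, x0 = 0, x1 = 2, mask = mask)
  expect_equal(crm$counts[, 2, 2], rep(0, 8))
  expect_error(crop_image(img, y0 = 5, y1 = 3), "invalid")
})

test_that("intensity thresholding masks pixels without disturbing the rest", {
  g <- std_grid(64)
  set.seed(131)
  bright <- rpois(64, flimfit:::expected_transient(
    decay_model(Z = 0, A = 1, tau = 2), g, 3000))
  dim_px <- rpois(64, flimfit:::expected_transient(
    decay_model(Z = 0, A = 1, tau = 2), g, 50))
  counts <- array(0, dim = c(64, 2, 2))
  counts[, 1, 1] <- bright; counts[, 1, 2] <- bright
  counts[, 2, 1] <- dim_px; counts[, 2, 2] <- bright
  img <- flim_image(counts, g)
  m <- fit_image(img, "rld", intensity_threshold = 1000)
  expect_false(m$mask[2, 1])
  expect_true(all(is.nan(sapply(m$maps, function(mp) mp[2, 1]))))
  # raising the threshold leaves surviving pixels bit-identical
  m2 <- fit_image(img, "rld", intensity_threshold = 2000)
  expect_identical(m2$maps$tau1[1, 1], m$maps$tau1[1, 1])
  expect_error(fit_image(img, "rld", intensity_threshold = 1e9),
               "threshold")
})

test_that("uniform images reproduce the single-transient fit at every pixel", {
  g <- std_grid(64)
  set.seed(137)
  y <- rpois(64, flimfit:::expected_transient(
    decay_model(Z = 0, A = 1, tau = 1.8), g, 4000))
  counts <- array(rep(y, 9), dim = c(64, 3, 3))
  img <- flim_image(counts, g)
  d <- decay_curve(y, g)

  m_rld <- fit_image(img, "rld")
  ref_rld <- coef(fit_rld(d))
  expect_identical(unname(m_rld$maps$tau1[2, 2]), unname(ref_rld["tau1"]))

  m_lma <- fit_image(img, "lma")
  ref_lma <- coef(fit_lma(d))
  expect_equal(unname(m_lma$maps$tau1[3, 1]), unname(ref_lma["tau1"]),
               tolerance = 1e-9)

  m_ph <- fit_image(img, "phasor")
  ref_ph <- phasor_transform(d)
  expect_equal(unname(m_ph$maps$g[1, 3]), ref_ph$g, tolerance = 1e-12)
  expect_equal(unname(m_ph$maps$tau_phase[1, 1]), ref_ph$tau_phase,
               tolerance = 1e-12)

  m_b <- fit_image(img, "bayes", grid_size = c(80, 80))
  ref_b <- fit_bayes(d, grid_size = c(80, 80))
  expect_equal(unname(m_b$maps$tau1[2, 3]), coef(ref_b)[["tau1"]],
               tolerance = 1e-9)
})

test_that("per-pixel fits are independent of chunking", {
  sim <- simulate_onecomp_image(size = c(4, 6), n_levels = 4,
                                photons_per_pixel = 2000, seed = 139)
  a <- fit_image(sim$image, "lma", chunk_size = 5)
  b <- fit_image(sim$image, "lma", chunk_size = 1024)
  expect_equal(a$maps$tau1, b$maps$tau1, tolerance = 1e-12)
  a_r <- fit_image(sim$image, "rld", chunk_size = 3)
  b_r <- fit_image(sim$image, "rld")
  expect_identical(a_r$maps$tau1, b_r$maps$tau1)
})

test_that("mean-lifetime maps implement both weightings", {
  maps <- structure(list(
    maps = list(Z = matrix(0, 1, 1), A1 = matrix(1, 1, 1),
                A2 = matrix(1, 1, 1), tau1 = matrix(1, 1, 1),
                tau2 = matrix(3, 1, 1)),
    mask = matrix(TRUE, 1, 1), method = "lma", n_components = 2),
    class = "flim_maps")
  expect_equal(mean_lifetime_map(maps, "amplitude")[1, 1], 2.0)
  expect_equal(mean_lifetime_map(maps, "intensity")[1, 1], 2.5)

  maps1 <- structure(list(
    maps = list(Z = matrix(0, 2, 2), A1 = matrix(4, 2, 2),
                tau1 = matrix(1.7, 2, 2)),
    mask = matrix(TRUE, 2, 2), method = "lma", n_components = 1),
    class = "flim_maps")
  expect_equal(mean_lifetime_map(maps1), maps1$maps$tau1)

  # non-positive amplitude sum gives NaN
  maps$maps$A1[1, 1] <- -1
  expect_true(is.nan(mean_lifetime_map(maps, "amplitude")[1, 1]))
})

test_that("FRET efficiency follows 1 - T_DA / T_D", {
  fr <- fret_efficiency(2.23, 2.16)
  expect_equal(fr$efficiency, 1 - 2.16 / 2.23, tolerance = 1e-12)
  expect_equal(round(100 * fr$efficiency, 1), 3.1)
  expect_equal(fret_efficiency(2, 2)$efficiency, 0)
  expect_equal(fret_efficiency(2, 0)$efficiency, 1)
  # map input
  td <- matrix(c(2, 2.5, 3, 4), 2, 2)
  tda <- matrix(c(1, 2.5, 1.5, 5), 2, 2)
  frm <- fret_efficiency(td, tda)
  expect_equal(frm$efficiency, 1 - tda / td)
  expect_error(fret_efficiency(0, 1), "positive")
  expect_error(fret_efficiency(-2, 1), "positive")
})

test_that("two-component per-pixel maps reproduce the fraction gradient", {
  sim <- simulate_twocomp_image(size = c(12, 12), photons_per_pixel = 8000,
                                seed = 149)
  m <- fit_image(sim$image, "global", n_components = 2)
  frac <- m$maps$A1 / (m$maps$A1 + m$maps$A2)
  truth <- sim$truth$A1 / (sim$truth$A1 + sim$truth$A2)
  expect_gt(cor(as.vector(frac), as.vector(truth)), 0.98)
  # lifetimes exposed as constant maps
  expect_equal(unname(m$maps$tau2[5, 5]), 2.1, tolerance = 0.1)
})
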