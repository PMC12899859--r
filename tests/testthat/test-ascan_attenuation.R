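test_that("ROI extraction uses the inclusive-exclusive pixel convention", {
  b <- bscan(matrix(runif(1000 * 1000), 1000, 1000), 0.003, 0.004)
  sub <- extract_roi(b, roi_spec(50, 100, 40, 900))
  expect_equal(dim(sub$intensity), c(860L, 50L))
  expect_equal(sub$depth_origin, 40 * 0.003)
  expect_equal(sub$intensity[1, 1], b$intensity[41, 51])

  full <- extract_roi(b, roi_spec(0, 1000, 0, 1000))
  expect_identical(full$intensity, b$intensity)
  expect_error(roi_spec(50, 50, 0, 10), "min < max")
  expect_error(extract_roi(b, roi_spec(0, 1001, 0, 10)), "bounds")
})

test_that("Gaussian denoising preserves DC, mass and the identity at sigma 0", {
  m <- matrix(runif(60 * 40), 60, 40)
  b <- bscan(m, 0.003, 0.004)
  expect_identical(denoise_gaussian(b, 0)$intensity, m)
  const <- bscan(matrix(0.7, 30, 30), 0.003, 0.004)
  expect_equal(denoise_gaussian(const, 1)$intensity, const$intensity,
               tolerance = 1e-12)
  # impulse response is the separable sampled-Gaussian kernel, s.d. 1 px
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  d <- denoise_gaussian(bscan(imp, 0.003, 0.004), 1)$intensity
  expect_equal(sum(d), 1, tolerance = 1e-3)
  w <- d[11 + (-4:4), 11]; w <- w / sum(w)
  expect_equal(sqrt(sum(w * (-4:4)^2)), 1, tolerance = 1e-3)
  expect_error(denoise_gaussian(b, -1), ">= 0")
})

test_that("lateral mean averages rows and carries absolute depth", {
  m <- matrix(c(1, 2, 0, 3, 2, 4), nrow = 3)   # rows (1,3),(2,2),(0,4)
  a <- lateral_mean(bscan(m, 0.003, 0.004))
  expect_equal(a$intensity, c(2, 2, 2))
  expect_equal(a$depth, c(0, 0.003, 0.006))
  one_col <- lateral_mean(bscan(matrix(c(5, 6, 7), 3, 1), 0.003, 0.004))
  expect_equal(one_col$intensity, c(5, 6, 7))
})

test_that("Savitzky-Golay smoothing reproduces polynomials up to its order", {
  z <- (0:199) * 0.003
  cubic <- 2 + 3 * z - 40 * z^2 + 100 * z^3
  a <- savgol_smooth(ascan(z, cubic), 11, 3)
  expect_equal(a$intensity, cubic, tolerance = 1e-10)
  const <- savgol_smooth(ascan(z, rep(1, 200)), 11, 3)
  expect_equal(const$intensity, rep(1, 200), tolerance = 1e-12)
  expect_error(savgol_smooth(ascan(z[1:5], rep(1, 5)), 11, 3), "shorter")
  expect_error(savgol_smooth(ascan(z, cubic), 10, 3), "odd")
})

test_that("peak detection honours prominence, spacing and depth limits", {
  z <- (0:999) * 0.003
  flat <- ascan(z, rep(0.5, 1000))
  expect_equal(length(detect_peaks(flat)), 0L)

  # two equal peaks 10 px apart: spacing rule keeps the shallower one
  y <- rep(0.1, 1000); y[c(100, 110)] <- 1
  pk <- detect_peaks(ascan(z, y), min_spacing = 20)
  expect_equal(pk$indices, 100L)

  # layered phantom: detected depths match the generator's interfaces
  b <- make_layered_bscan(0.916, seed = 5, speckle = FALSE, noise_sigma = 0)
  cfg <- wide_roi_config()
  sm <- savgol_smooth(lateral_mean(denoise_gaussian(
    extract_roi(b, cfg$roi), 1)), 11, 3)
  pk2 <- detect_peaks(sm, 20, 0.005, 2.5)
  truth_z <- seq(0.12, 2.5, by = 0.081)
  matched <- vapply(pk2$depths,
                    function(d) min(abs(d - truth_z)), numeric(1))
  expect_true(all(matched <= 0.003))
  expect_true(all(pk2$depths <= 2.5))
  expect_true(all(diff(pk2$depths) > 0))
})

test_that("two-way decay fit recovers exact parameters from model peaks", {
  for (mu in c(0.916, 1.224)) {
    fit <- fit_two_way_decay(make_decay_peaks(mu))
    expect_equal(fit$mu, mu, tolerance = 1e-6 * mu)
    expect_equal(fit$i0, 1, tolerance = 1e-6)
    expect_equal(fit$c0, 0.01, tolerance = 1e-4)
    expect_equal(fit$r2, 1, tolerance = 1e-10)
    expect_equal(fit$z0, 0.12)
  }
  # flat peaks give mu = 0
  flat <- peak_set((0:9) * 0.081 + 0.1, rep(0.4, 10), 1:10)
  expect_equal(fit_two_way_decay(flat)$mu, 0, tolerance = 1e-8)
  expect_error(fit_two_way_decay(make_decay_peaks(1, n = 2)), "at least 3")
})

test_that("one-way model fits exactly twice the two-way coefficient", {
  pk <- make_decay_peaks(1.224)
  f2 <- fit_two_way_decay(pk, two_way = TRUE)
  f1 <- fit_two_way_decay(pk, two_way = FALSE)
  expect_equal(f1$mu, 2 * f2$mu, tolerance = 1e-8)
})

test_that("fit R2 is 1 noise-free and decreases with noise amplitude", {
  pk <- make_decay_peaks(1.0)
  r2 <- numeric(3)
  noise <- c(0, 0.01, 0.05)
  set.seed(8)
  for (i in 1:3) {
    I <- pk$intensities * exp(rnorm(length(pk$intensities), sd = noise[i]))
    r2[i] <- fit_two_way_decay(peak_set(pk$depths, I, pk$indices))$r2
  }
  expect_equal(r2[1], 1, tolerance = 1e-10)
  expect_true(all(diff(r2) < 0))
})

test_that("full pipeline recovers the generator decay end to end", {
  # noise-free layered phantom (Sample B OCT coefficient)
  b <- make_layered_bscan(1.224, seed = 1, speckle = FALSE, noise_sigma = 0,
                          cols = 100L)
  fit <- estimate_attenuation(b, wide_roi_config(100L))
  expect_equal(fit$mu, 1.224, tolerance = 1e-3)
  expect_equal(fit$stages,
               c("extract_roi", "denoise_gaussian", "lateral_mean",
                 "savgol_smooth", "detect_peaks", "fit_two_way_decay"))

  # flat phantom: mu ~ 0
  b0 <- make_layered_bscan(0, seed = 2, speckle = FALSE, noise_sigma = 0,
                           cols = 100L)
  expect_lt(estimate_attenuation(b0, wide_roi_config(100L))$mu, 1e-6)

  # determinism: identical input and config give identical fits
  b1 <- make_layered_bscan(0.916, seed = 3)
  f1 <- estimate_attenuation(b1, wide_roi_config())
  f2 <- estimate_attenuation(b1, wide_roi_config())
  expect_identical(f1$mu, f2$mu)

  # speckled single run stays within 10 percent (Sample C OCT coefficient)
  expect_lt(abs(f1$mu / 0.916 - 1), 0.10)
})

test_that("pipeline errors carry their stage label", {
  b <- make_layered_bscan(1, seed = 4, cols = 50L)
  bad <- run_config(roi = roi_spec(0, 2000, 40, 900))
  expect_error(estimate_attenuation(b, bad), "extract_roi")
  flat <- bscan(matrix(0.5, 1000, 50), 0.003, 0.004)
  expect_error(estimate_attenuation(flat, wide_roi_config(50L)),
               "fit_two_way_decay")
})
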