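test_that("noise-free B-scan matches the closed-form decay envelope", {
  # flat case: mu = 0 gives I0 at and below the surface
  tr0 <- ground_truth(mu = 0, i0 = 0.8, c0 = 0.1, z0 = 0.06,
                      speckle = FALSE, noise_sigma = 0)
  b0 <- gen_bscan(tr0, shape = c(100L, 5L), axial_pitch = 0.003)
  z <- (0:99) * 0.003
  expect_true(all(abs(b0$intensity[z >= 0.06, ] - 0.8) < 1e-12))
  expect_true(all(abs(b0$intensity[z < 0.06, ] - 0.1) < 1e-12))

  # decaying case evaluated 1 mm below the surface (Sample B OCT mu);
  # 0.0025 mm/px puts both the surface and the +1 mm point on the grid
  tr <- ground_truth(mu = 1.224, i0 = 1, c0 = 0.01, z0 = 0.12,
                     speckle = FALSE, noise_sigma = 0)
  b <- gen_bscan(tr, shape = c(500L, 4L), axial_pitch = 0.0025)
  row_1mm <- 1L + as.integer(round(1.12 / 0.0025))
  expect_equal(mean(b$intensity[row_1mm, ]),
               (1 - 0.01) * exp(-2 * 1.224 * 1) + 0.01, tolerance = 1e-12)
})

test_that("generators are deterministic under a fixed seed", {
  tr <- ground_truth(mu = 1, seed = 99)
  b1 <- gen_bscan(tr, shape = c(120L, 30L))
  b2 <- gen_bscan(tr, shape = c(120L, 30L))
  expect_identical(b1$intensity, b2$intensity)
  r1 <- gen_rolloff(noise_sigma = 0.5, seed = 5)
  r2 <- gen_rolloff(noise_sigma = 0.5, seed = 5)
  expect_identical(r1$sensitivity, r2$sensitivity)
  expect_error(gen_bscan(ground_truth(z0 = 2), shape = c(100L, 5L)),
               "beyond")
})

test_that("speckle is mean-preserving on the lateral average", {
  tr <- ground_truth(mu = 1.5, i0 = 1, c0 = 0.02, z0 = 0.09,
                     speckle = TRUE, noise_sigma = 0, seed = 21)
  b <- gen_bscan(tr, shape = c(400L, 600L), axial_pitch = 0.003)
  z <- (0:399) * 0.003
  envelope <- ifelse(z >= 0.09,
                     (1 - 0.02) * exp(-2 * 1.5 * (z - 0.09)) + 0.02, 0.02)
  lat <- rowMeans(b$intensity)
  # exponential speckle: s.d. equals the mean, averaged over 600 columns
  se <- envelope / sqrt(600)
  frac_within <- mean(abs(lat - envelope) <= 3 * se)
  expect_gt(frac_within, 0.98)
})

test_that("PSF generator hits the requested FWHM and peak position", {
  p <- gen_psf_ascan(fwhm = 16.30, center = 0.094, noise_sigma = 0)
  expect_lt(abs(p$depth[which.max(p$intensity)] - 0.094), 0.0031)
  half_width_um <- function(a) {
    y <- a$intensity / max(a$intensity)
    above <- which(y >= 0.5)
    i1 <- above[1]; i2 <- above[length(above)]
    xl <- approx(y[(i1 - 1):i1], a$depth[(i1 - 1):i1], xout = 0.5)$y
    xr <- approx(y[i2:(i2 + 1)], a$depth[i2:(i2 + 1)], xout = 0.5)$y
    (xr - xl) * 1000
  }
  expect_equal(half_width_um(p), 16.30, tolerance = 0.3)
  # doubling the FWHM doubles the crossing separation
  p2 <- gen_psf_ascan(fwhm = 32.60, center = 0.094, noise_sigma = 0)
  expect_equal(half_width_um(p2) / half_width_um(p), 2, tolerance = 0.02)
  expect_error(gen_psf_ascan(center = 99), "outside")
  expect_error(gen_psf_ascan(fwhm = -1), "> 0")
})

test_that("roll-off generator is linear in dB with the stated 6 dB depth", {
  r <- gen_rolloff(depths = seq(0, 2.5, 0.1), s0 = 30, z6db = 1.81,
                   noise_sigma = 0)
  expect_equal(r$sensitivity[1], 30)
  s_at <- approx(r$depth, r$sensitivity, xout = 1.81)$y
  expect_equal(s_at, 30 - 6, tolerance = 1e-12)
  expect_true(all(abs(diff(r$sensitivity) + 6 * 0.1 / 1.81) < 1e-12))
  expect_error(gen_rolloff(z6db = 0), "> 0")
})

test_that("spectro series generator follows Beer-Lambert and conserves energy", {
  s <- gen_spectro_series(2, thicknesses = c(0.5, 1, 1.5),
                          surface_reflectance = 0.1)
  expect_equal(s$transmittance[1], exp(-1), tolerance = 1e-12)
  expect_true(all(s$reflectance + s$transmittance <= 1))
  # Sample C UV-VIS mu_eff as forward input
  s2 <- gen_spectro_series(3.103, thicknesses = c(0.5, 1, 2),
                           surface_reflectance = 0.04)
  expect_equal(s2$transmittance[2], exp(-3.103), tolerance = 1e-12)
  expect_error(gen_spectro_series(-1), ">= 0")
  expect_error(gen_spectro_series(0.1, thicknesses = 0.1,
                                  surface_reflectance = 0.5), "exceeds 1")
})

test_that("step phantom renders recoverable plateaus", {
  # six uniform 0.4 mm steps over a 6 mm length: 6 plateaus
  sp <- step_phantom_spec(rep(0.4, 6), step_width = 1.0, total_length = 6.0)
  b <- gen_step_bscan(sp, axial_pitch = 0.003, lateral_pitch = 0.004)
  prof <- surface_profile(b)
  expect_equal(length(unique(prof)), 6L)
  # recovered rises match the spec within one pixel
  levels <- unique(prof)
  rises <- -diff(levels)
  expect_true(all(abs(rises - 0.4) <= 0.003))

  # a single step on a longer base: 2 plateaus
  sp1 <- step_phantom_spec(0.5, step_width = 1.0, total_length = 2.0)
  b1 <- gen_step_bscan(sp1)
  expect_equal(length(unique(surface_profile(b1))), 2L)
  expect_error(step_phantom_spec(rep(0.4, 20), 1.0, total_length = 6),
               "fit")
})
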