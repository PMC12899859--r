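test_that("absorption fraction is the energy-balance remainder", {
  expect_equal(absorption_fraction(0.3, 0.6), 0.1)
  expect_equal(absorption_fraction(0.5, 0.5), 0.0)
  expect_equal(absorption_fraction(0, 0), 1.0)
  expect_error(absorption_fraction(0.7, 0.4), "non-physical")
  expect_error(absorption_fraction(1.2, 0), "0, 1")
})

test_that("Beer-Lambert inversion matches its closed form and round-trips", {
  expect_equal(beer_lambert_mu_t(1, 0.08), 0)
  expect_equal(beer_lambert_mu_t(exp(-2), 1), 2)
  expect_equal(beer_lambert_mu_t(0.5, 0.08), log(2) / 0.08,
               tolerance = 1e-12)               # ~8.6643 for a 0.08 mm film
  expect_error(beer_lambert_mu_t(0, 1), "infinite")
  expect_error(beer_lambert_mu_t(1.1, 1), "exceed")
  expect_equal(beer_lambert_transmittance(2, 0), 1)

  # property: round trip to 1e-10 relative over a parameter grid
  for (mu in c(0.01, 0.5, 3.103, 20))
    for (d in c(0.05, 0.5, 5)) {
      expect_equal(beer_lambert_mu_t(beer_lambert_transmittance(mu, d), d),
                   mu, tolerance = 1e-10)
    }
})

test_that("diffusion-approximation inversion round-trips the forward model", {
  # forward mu_eff for (mu_a 0.1, mu_s 2, g 0.9) then invert
  expect_equal(mu_s_from_diffusion(mu_eff_diffusion(0.1, 2, 0.9), 0.1, 0.9),
               2, tolerance = 1e-12)
  # zero-scattering limit
  expect_equal(mu_s_from_diffusion(sqrt(3) * 0.2, 0.2, 0.9), 0,
               tolerance = 1e-9)
  # doubling (1 - g) halves the result at fixed mu_eff, mu_a
  r1 <- mu_s_from_diffusion(1.5, 0.1, 0.9)
  r2 <- mu_s_from_diffusion(1.5, 0.1, 0.8)
  expect_equal(r1 / r2, 2, tolerance = 1e-12)
  expect_error(mu_s_from_diffusion(1, 0), "> 0")
  expect_error(mu_s_from_diffusion(0.1, 0.5), "negative scattering")

  # property grid, 1e-10 relative
  for (mu_a in c(0.05, 0.16, 1))
    for (mu_s in c(0.5, 3, 10))
      for (g in c(0, 0.5, 0.9)) {
        expect_equal(
          mu_s_from_diffusion(mu_eff_diffusion(mu_a, mu_s, g), mu_a, g),
          mu_s, tolerance = 1e-10)
      }
})

test_that("subtractive decomposition is exact, linear and monotone", {
  expect_identical(mu_s_subtractive(3.103, 0.10), 3.003)
  expect_identical(mu_s_subtractive(1.016, 0.10), 0.916)
  expect_equal(mu_s_subtractive(5, 0), 5)
  expect_error(mu_s_subtractive(0.1, 0.2), "negative")
  x <- seq(1, 4, by = 0.5)
  expect_equal(diff(mu_s_subtractive(x, 0.1)), diff(x))
})

test_that("thickness-series fit is exact on noise-free data and validates input", {
  s <- gen_spectro_series(3.103, thicknesses = (1:6) * 0.07,
                          surface_reflectance = 0.04)
  fit <- fit_mu_eff_vs_thickness(s)
  expect_equal(fit$mu_eff, 3.103, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # constant T = 1 gives mu_eff = 0
  s1 <- spectro_series((1:4) * 0.1, rep(840, 4), rep(0, 4), rep(1, 4))
  expect_equal(fit_mu_eff_vs_thickness(s1)$mu_eff, 0)

  s2 <- spectro_series(c(0.1, 0.2), c(840, 840), c(0, 0), c(0.9, 0.8))
  expect_error(fit_mu_eff_vs_thickness(s2), "at least 3")

  # wavelength selection: 840 nm rows picked from a mixed series
  mix <- spectro_series(rep((1:3) * 0.1, 2), rep(c(840, 900), each = 3),
                        rep(0.04, 6),
                        c(exp(-2 * (1:3) * 0.1), exp(-5 * (1:3) * 0.1)))
  f840 <- fit_mu_eff_vs_thickness(mix, at_nm = 841)
  expect_equal(f840$mu_eff, 2, tolerance = 1e-10)
  expect_error(fit_mu_eff_vs_thickness(mix, at_nm = 600), "no rows")
})

test_that("thickness-series fit is unbiased under multiplicative noise", {
  mus <- vapply(1:200, function(i) {
    s <- gen_spectro_series(2.5, thicknesses = (1:6) * 0.1,
                            surface_reflectance = 0.04,
                            noise_cv = 0.02, seed = 1000 + i)
    fit_mu_eff_vs_thickness(s)$mu_eff
  }, numeric(1))
  se <- sd(mus) / sqrt(length(mus))
  expect_lt(abs(mean(mus) - 2.5), 3 * se)
})

test_that("optical property bundle enforces the reduced-scattering identity", {
  ok <- optical_properties(mu_a = 0.1, mu_s = 2, mu_s_reduced = 0.2, g = 0.9)
  expect_equal(ok$mu_s_reduced, (1 - ok$g) * ok$mu_s)
  expect_error(optical_properties(mu_s = 2, mu_s_reduced = 1, g = 0.9),
               "inconsistent")
  expect_error(optical_properties(mu_a = -1), ">= 0")
  expect_error(optical_properties(g = 1), "0, 1")
})
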