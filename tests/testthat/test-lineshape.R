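# Forward spectral model: resolution profile, detailed balance, DHO kernel,
# convolution, and full model evaluation against an independent oracle.

test_that("Pseudo-Voigt peak heights match the unit-area closed forms", {
  expect_equal(pseudo_voigt(0, resolution_function(1.7, eta = 1)),
               2 / (pi * 1.7), tolerance = 1e-10)
  expect_equal(pseudo_voigt(0, resolution_function(1.7, eta = 0)),
               (2 / 1.7) * sqrt(log(2) / pi), tolerance = 1e-10)
  # symmetric about zero
  w <- seq(0.1, 8, by = 0.7)
  rf <- resolution_function(1.7, 0.5)
  expect_equal(pseudo_voigt(w, rf), pseudo_voigt(-w, rf))
})

test_that("Pseudo-Voigt has unit area and the requested FWHM", {
  rf <- resolution_function(1.7, 0.5)
  area <- stats::integrate(function(w) pseudo_voigt(w, rf), -50, 50)$value
  expect_equal(area, 1, tolerance = 0.02)  # Lorentzian tails beyond +/-50

  step <- 0.001
  w <- seq(-10, 10, by = step)
  for (eta in c(0, 0.5, 1)) {
    rfe <- resolution_function(1.7, eta)
    y <- pseudo_voigt(w, rfe)
    above <- range(w[y >= max(y) / 2])
    expect_equal(diff(above), 1.7, tolerance = 2 * step)
  }
})

test_that("invalid resolution parameters are rejected", {
  expect_error(resolution_function(-1, 0.5), "positive")
  expect_error(resolution_function(0, 0.5), "positive")
  expect_error(resolution_function(1.7, 1.5), "\\[0, 1\\]")
})

test_that("detailed balance weight has the Stokes/anti-Stokes asymmetry", {
  expect_equal(detailed_balance_factor(0, 293.15), 1)
  kT <- 8.617333262e-2 * 293.15
  ratio <- detailed_balance_factor(2, 293.15) / detailed_balance_factor(-2, 293.15)
  expect_equal(ratio, exp(2 / kT), tolerance = 1e-12)
  expect_equal(ratio, 1.0824, tolerance = 1e-4)
  # linear asymptote at large positive energy (residual ~ x*exp(-x))
  expect_equal(detailed_balance_factor(500, 293.15), 500 / kT, tolerance = 1e-6)
  expect_error(detailed_balance_factor(1, -5), "positive")
})

test_that("DHO profile satisfies detailed balance on a grid to 1e-8", {
  m <- dho_mode(3, 1.2, 50)
  w <- seq(0.25, 14, by = 0.25)
  kT <- 8.617333262e-2 * 318.15
  ratio <- dho_profile(w, m, 318.15) / dho_profile(-w, m, 318.15)
  expect_equal(ratio, exp(w / kT), tolerance = 1e-8)
})

test_that("classical DHO kernel is even, unit-area and peaks near Omega", {
  m <- dho_mode(3, 0.5, 1)
  w <- seq(0.1, 20, by = 0.37)
  expect_equal(dho_profile(w, m, Inf), dho_profile(-w, m, Inf))

  for (pars in list(c(3, 0.5), c(5, 2), c(1, 3))) {
    mm <- dho_mode(pars[1], pars[2], 1)
    area <- stats::integrate(function(x) dho_profile(x, mm, Inf), -Inf, Inf,
                             rel.tol = 1e-10)$value
    expect_equal(area, 1, tolerance = 1e-4)
  }
  # underdamped (R = 6): spectral peak within 0.1 meV of Omega
  wg <- seq(0.01, 10, by = 0.005)
  expect_lt(abs(wg[which.max(dho_profile(wg, m, Inf))] - 3), 0.1)
  # integrated strength scales the area
  m2 <- dho_mode(3, 0.5, 100)
  expect_equal(stats::integrate(function(x) dho_profile(x, m2, Inf),
                                -Inf, Inf)$value, 100, tolerance = 0.01)
})

test_that("mode and parameter constructors validate their inputs", {
  expect_error(dho_mode(-1, 1, 1), "non-negative")
  expect_error(dho_mode(3, 0, 1), "positive")
  expect_error(dho_mode(3, 1, -2), "non-negative")
  expect_error(spectral_params(-1, 0, list(), 300), "non-negative")
  expect_error(spectral_params(1, 0, list(dho_mode(1, 1, 1), dho_mode(2, 1, 1),
                                          dho_mode(3, 1, 1)), 300), "0 to 2")
  expect_error(spectral_params(1, 0, list(), 0), "positive")
})

test_that("convolution reduces to the identity for a quasi-delta resolution", {
  grid <- seq(-15, 15, length.out = 97)
  dens <- function(w) dnorm(w, 0, 2)
  out <- convolve_with_rf(dens, resolution_function(1e-3, 0.5), grid)
  ref <- dens(grid)
  keep <- ref > 0.01 * max(ref)
  expect_lt(max(abs(out[keep] - ref[keep]) / ref[keep]), 0.005)
})

test_that("Lorentzian widths add under convolution with a Lorentzian RF", {
  grid <- seq(-15, 15, length.out = 97)
  a <- 2; b <- 1.7
  lor <- function(w, fwhm) (fwhm / (2 * pi)) / (w^2 + (fwhm / 2)^2)
  out <- convolve_with_rf(function(w) lor(w, a),
                          resolution_function(b, eta = 1), grid)
  exact <- lor(grid, a + b)
  expect_lt(max(abs(out - exact)) / max(exact), 0.01)
})

test_that("convolution conserves the zeroth moment of a padded density", {
  grid <- seq(-60, 60, by = 0.5)
  rf <- resolution_function(1.7, 0.5)
  out <- convolve_with_rf(function(w) dnorm(w, 0, 1.5), rf, grid)
  expect_equal(sum(out) * 0.5, 1, tolerance = 0.01)
  expect_error(convolve_with_rf(function(w) w, rf, c(0, 1)), "3")
})

test_that("model evaluation reduces correctly in degenerate limits", {
  grid <- seq(-15, 15, length.out = 97)
  rf <- resolution_function(1.7, 0.5)
  p0 <- spectral_params(120, 0, list(), 318)
  expect_equal(evaluate_model(p0, grid, rf), 120 * pseudo_voigt(grid, rf))
  pb <- spectral_params(0, 7, list(), 318)
  expect_equal(evaluate_model(pb, grid, rf), rep(7, 97))
})

test_that("model evaluation is linear in the amplitudes", {
  grid <- seq(-15, 15, length.out = 97)
  rf <- resolution_function(1.7, 0.5)
  p1 <- spectral_params(1000, 5, list(dho_mode(3, 1, 100),
                                      dho_mode(8, 2, 40, "longitudinal")), 318)
  c_fac <- 3.7
  p2 <- spectral_params(1000 * c_fac, 5 * c_fac,
                        list(dho_mode(3, 1, 100 * c_fac),
                             dho_mode(8, 2, 40 * c_fac, "longitudinal")), 318)
  expect_equal(evaluate_model(p2, grid, rf),
               c_fac * evaluate_model(p1, grid, rf), tolerance = 1e-12)
})

test_that("model evaluation matches an independent direct-quadrature oracle", {
  grid <- standard_grid()
  rf <- resolution_function(1.7, 0.5)
  params <- spectral_params(1000, 5, list(dho_mode(3, 1, 100)), 318)
  mine <- evaluate_model(params, grid, rf)
  ora <- oracle_model(params, grid, rf)
  expect_lt(max(abs(mine - ora)) / max(ora), 0.005)

  # frozen spot values produced by the oracle (golden evaluation)
  golden <- c(`0` = 473.364382, `3.125` = 33.461192,
              `-3.125` = 31.922034, `10` = 6.563951)
  idx <- match(as.numeric(names(golden)), round(grid, 4))
  expect_equal(unname(mine[idx]), unname(golden), tolerance = 0.01)
  # dominant central peak with inelastic shoulders
  expect_equal(grid[which.max(mine)], 0)
  expect_gt(mine[match(3.125, round(grid, 4))],
            mine[match(5.625, round(grid, 4))])
})
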