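# Least-squares fitting, chi-squared bookkeeping, the two-hump residual
# diagnostic, mode-count selection, and the statistical calibration of the
# fits on seeded synthetic ensembles.

test_that("noise-free spectra are recovered essentially exactly", {
  params <- spectral_params(5000, 20, list(dho_mode(5, 1.5, 300)), 318.15)
  sp <- noise_free_spectrum(params)
  fit <- fit_spectrum(sp, n_modes = 1, seed = 1)
  expect_true(fit$converged)
  expect_lt(fit$reduced_chi2, 1e-6)
  expect_equal(fit$params$elastic_amplitude, 5000, tolerance = 1e-3)
  expect_equal(fit$params$background, 20, tolerance = 1e-3)
  m <- fit$params$modes[[1]]
  expect_equal(m$omega0, 5, tolerance = 1e-3)
  expect_equal(m$gamma, 1.5, tolerance = 1e-3)
  expect_equal(m$intensity, 300, tolerance = 1e-3)
  expect_identical(m$label, "longitudinal")
})

test_that("fits are deterministic given spectrum and seed", {
  sc <- phase_scenario("fluid_45C")
  sp <- generate_spectrum(sc, 3.89, seed = 99)
  f1 <- fit_spectrum(sp, n_modes = 1, seed = 42)
  f2 <- fit_spectrum(sp, n_modes = 1, seed = 42)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$reduced_chi2, f2$reduced_chi2)
  expect_identical(f1$param_errors, f2$param_errors)
})

test_that("under-determined fits are refused", {
  rf <- resolution_function(1.7, 0.5)
  sp <- ixs_spectrum(seq(-3, 3, length.out = 7), rep(10, 7), rep(1, 7),
                     q = 2, temperature_C = 20, rf = rf)
  expect_error(fit_spectrum(sp, n_modes = 2), "under-determined")
})

test_that("reduced chi-squared follows its definition", {
  params <- spectral_params(5000, 20, list(dho_mode(5, 1.5, 300)), 318.15)
  sp <- noise_free_spectrum(params)
  expect_equal(reduced_chi_square(sp, params), 0)
  off <- ixs_spectrum(sp$energy, sp$intensity + sp$error, sp$error,
                      q = 5, temperature_C = 45,
                      rf = resolution_function(1.7, 0.5))
  expect_equal(reduced_chi_square(off, params), 97 / 92, tolerance = 1e-10)
  tiny <- ixs_spectrum(seq(-1, 1, length.out = 5),
                       rep(10, 5), rep(1, 5), q = 1, temperature_C = 45,
                       rf = resolution_function(1.7, 0.5))
  expect_error(reduced_chi_square(tiny, params), "free parameters")
})

test_that("two-hump diagnostic needs two symmetric positive lobes", {
  grid <- seq(-15, 15, length.out = 97)
  expect_false(two_hump_diagnostic(rep(0, 97), grid)$two_hump)

  withr::with_seed(7, {
    noise <- rnorm(97)
    bumps <- 3 * exp(-(grid - 2)^2 / 0.5) + 3 * exp(-(grid + 2)^2 / 0.5)
    res <- two_hump_diagnostic(noise + bumps, grid)
    expect_true(res$two_hump)
    expect_equal(res$omega_pos, 2, tolerance = 0.5)
    expect_equal(res$omega_neg, -2, tolerance = 0.5)
    one_sided <- two_hump_diagnostic(noise + 3 * exp(-(grid - 2)^2 / 0.5), grid)
    expect_false(one_sided$two_hump)
  })
})

test_that("adding a mode never increases the minimized sum of squares", {
  scg <- phase_scenario("gel_20C")
  scf <- phase_scenario("fluid_45C")
  cases <- list(list(scg, 9.77), list(scg, 2.47), list(scf, 3.93),
                list(scf, 14.15))
  for (cs in cases) {
    sp <- generate_spectrum(cs[[1]], cs[[2]], seed = 31)
    sel <- select_mode_count(sp, seed = 31)
    expect_lte(sel$fit_two[[1]]$ssr, sel$fit_one[[1]]$ssr + 1e-6)
  }
})

test_that("a second mode shows vanishing behavior when only one is real", {
  scf <- phase_scenario("fluid_45C")
  vanish_like <- 0
  for (s in 1:10) {
    sp <- generate_spectrum(scf, 3.93, seed = 400 + s)  # inside the gap
    sel <- select_mode_count(sp, seed = 400 + s)
    t2 <- tidy(sel$fit_two[[1]])
    i <- t2$estimate[c(5, 8)]
    si <- t2$std.error[c(5, 8)]
    vanish_like <- vanish_like + any(i < si | i < 0.02 * max(i))
  }
  expect_gte(vanish_like, 5)
})

test_that("parameter recovery is calibrated on a seeded synthetic ensemble", {
  scf <- phase_scenario("fluid_45C")
  truth <- true_dispersion(scf, "longitudinal", 3.89)
  n_rep <- 100
  om <- so <- gm <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sp <- generate_spectrum(scf, 3.89, seed = 7000 + r)
    f <- fit_spectrum(sp, n_modes = 1, seed = 7000 + r)
    om[r] <- f$params$modes[[1]]$omega0
    gm[r] <- f$params$modes[[1]]$gamma
    so[r] <- f$param_errors[["omega1"]]
  }
  # median relative bias of the recovered energy and width below 5%
  expect_lt(abs(median((om - truth$omega) / truth$omega)), 0.05)
  expect_lt(abs(median((gm - truth$gamma) / truth$gamma)), 0.05)
  # nominal 1-sigma intervals cover the truth at roughly Gaussian rates
  coverage <- mean(abs(om - truth$omega) <= so)
  expect_gte(coverage, 0.60)
  expect_lte(coverage, 0.80)
})

test_that("tidy and glance expose the fit in broom style", {
  sc <- phase_scenario("gel_20C")
  sp <- generate_spectrum(sc, 9.77, seed = 5)
  fit <- fit_spectrum(sp, n_modes = 2, seed = 5)
  td <- tidy(fit)
  expect_identical(td$term[1:2], c("elastic_amplitude", "background"))
  expect_identical(nrow(td), 8L)
  expect_true(all(c("transverse", "longitudinal") %in% td$branch))
  expect_true(all(td$std.error >= 0))
  gl <- glance(fit)
  expect_identical(gl$nobs, 97L)
  expect_identical(gl$n_free_params, 8L)
  expect_equal(gl$q, 9.77)
})
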