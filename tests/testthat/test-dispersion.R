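# Branch assembly, sound speeds, the dispersion minimum, area per lipid,
# damping ratios, gap detection, and the end-to-end recovery property.

fake_branches <- function(q, omega, branch = "longitudinal",
                          omega_err = rep(0.1, length(q)),
                          present = rep(TRUE, length(q))) {
  tibble::tibble(q = q, branch = branch, present = present,
                 omega = omega, omega_err = omega_err,
                 gamma = rep(1, length(q)), gamma_err = rep(0.1, length(q)),
                 intensity = rep(100, length(q)))
}

test_that("sound speed converts an exactly linear branch with the hbar factor", {
  q <- c(2, 4, 6, 8)
  ss <- sound_speed(fake_branches(q, 1.0 * q), q_linear_max = 8)
  expect_equal(ss$speed_m_s, 1519.2674, tolerance = 1e-3)
  ss2 <- sound_speed(fake_branches(q, 2.0 * q), q_linear_max = 8)
  expect_equal(ss2$speed_m_s, 2 * ss$speed_m_s)
  ss3 <- sound_speed(fake_branches(q, 1.667 * q), q_linear_max = 8)
  expect_equal(ss3$speed_m_s, 2532.6, tolerance = 1e-3)
})

test_that("sound speed is invariant under subsampling of a linear branch", {
  q <- seq(0.5, 8, by = 0.5)
  full <- sound_speed(fake_branches(q, 1.3 * q), q_linear_max = 8)
  sub <- sound_speed(fake_branches(q[c(2, 7, 13)], 1.3 * q[c(2, 7, 13)]),
                     q_linear_max = 8)
  expect_equal(full$speed_m_s, sub$speed_m_s, tolerance = 1e-10)
  expect_error(sound_speed(fake_branches(1, 1.3), q_linear_max = 8),
               "at least 2")
})

test_that("the dispersion minimum is located by local parabolic interpolation", {
  q <- c(14, 15, 16, 17)
  qm <- find_q_min(fake_branches(q, (q - 15.4)^2 + 2), window = c(13, 18))
  expect_false(qm$at_edge)
  expect_equal(qm$q_min, 15.4, tolerance = 0.05)

  mono <- find_q_min(fake_branches(10:16, 0.5 * (10:16)), window = c(10, 16))
  expect_true(mono$at_edge)
  expect_error(find_q_min(fake_branches(c(14, 15), c(2, 3)), window = c(13, 18)),
               "at least 3")
})

test_that("area per lipid reproduces the printed closed-form values", {
  a <- area_per_lipid(c(15.4, 14.2, 2 * pi))
  expect_equal(a$area_A2[1], 55.6, tolerance = 0.1)
  expect_equal(a$area_A2[2], 65.4, tolerance = 0.1)
  expect_equal(a$area_A2[3], 2.64 * 11.25^2, tolerance = 1e-9)
  # strictly decreasing in q_min
  grid <- area_per_lipid(seq(5, 25, by = 0.5))
  expect_true(all(diff(grid$area_A2) < 0))
  expect_error(area_per_lipid(-3), "positive")
})

test_that("damping ratio classifies over/critical/underdamped uniquely", {
  b <- fake_branches(c(1, 2, 3), c(2, 3, 1))
  b$gamma <- c(2, 0.5, 4)
  b$gamma_err <- c(0.01, 0.01, 0.01)
  b$omega_err <- c(0.01, 0.01, 0.01)
  r <- damping_ratio(b)
  expect_equal(r$R, c(1, 6, 0.25))
  expect_identical(r$regime, c("critical", "underdamped", "overdamped"))
  # exactly one regime per present point on a random branch
  withr::with_seed(3, {
    b2 <- fake_branches(1:20, runif(20, 0.5, 8))
    b2$gamma <- runif(20, 0.3, 6)
    r2 <- damping_ratio(b2)
    expect_true(all(r2$regime %in% c("critical", "underdamped", "overdamped")))
  })
  bad <- b; bad$gamma[2] <- 0
  expect_error(damping_ratio(bad), "positive")
})

test_that("gap detection applies the midpoint rule and its edge cases", {
  q <- c(2.47, 3.89, 5.2, 6.6, 8.1)
  gap <- detect_phonon_gap(
    fake_branches(q, c(NA, NA, 1.9, 2.2, 2.5), branch = "transverse",
                  present = c(FALSE, FALSE, TRUE, TRUE, TRUE)))
  expect_true(gap$gap_found)
  expect_equal(gap$q_gap, (3.89 + 5.2) / 2)

  all_there <- detect_phonon_gap(
    fake_branches(q, seq(1, 3, length.out = 5), branch = "transverse"))
  expect_false(all_there$gap_found)

  expect_warning(
    none <- detect_phonon_gap(
      fake_branches(q, rep(NA_real_, 5), branch = "transverse",
                    present = rep(FALSE, 5))),
    "no transverse")
  expect_false(none$gap_found)
})

test_that("cluster size is 2*pi/Q_gap and decreasing", {
  cs <- cluster_size(c(5, 2 * pi, 3.9))
  expect_equal(cs$d_gap_nm[1], 2 * pi / 5, tolerance = 1e-12)
  expect_gt(cs$d_gap_nm[1], 1.1)
  expect_lt(cs$d_gap_nm[1], 1.6)
  expect_equal(cs$d_gap_nm[2], 1)
  expect_equal(cs$d_gap_nm[3], 1.611, tolerance = 1e-3)
  grid <- cluster_size(seq(2, 10, by = 0.25))
  expect_true(all(diff(grid$d_gap_nm) < 0))
  expect_error(cluster_size(0), "positive")
})

test_that("branch assembly encodes mode presence and rejects bad input", {
  scf <- phase_scenario("fluid_45C")
  spectra <- lapply(c(2.47, 5.39, 9.77),
                    function(q) generate_spectrum(scf, q, seed = 21))
  fits <- fit_dataset(spectra, seed = 21)
  br <- assemble_branches(fits)
  expect_identical(nrow(br), 6L)  # two branches x three Q
  long <- br[br$branch == "longitudinal", ]
  expect_true(all(long$present))
  trans <- br[br$branch == "transverse", ]
  expect_false(trans$present[trans$q == 2.47])  # inside the gap
  expect_true(all(is.na(trans$omega[!trans$present])))

  dup <- fits[c(1, 1), ]
  expect_error(assemble_branches(dup), "duplicate")
  expect_error(assemble_branches(fits[0, ]), "")

  single <- assemble_branches(fits[2, ])
  expect_identical(nrow(single), 2L)
})

test_that("the full pipeline recovers the fluid-phase scenario truth", {
  scf <- phase_scenario("fluid_45C")
  spacing <- diff(scf$q_list)[1]
  n_seeds <- 20
  ok <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    ds <- generate_dataset(scf, seed = s)
    res <- analyze_dataset(ds$spectra, seed = s)
    d <- res$derived
    ok[s] <- isTRUE(abs(d$v_long - 2241) / 2241 <= 0.15) &&
      isTRUE(abs(d$area_A2 - 65.4) <= 2) &&
      isTRUE(d$gap_found) && isTRUE(abs(d$q_gap - 5) <= spacing)
  }
  expect_gte(mean(ok), 0.9)
})
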