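# Forward simulator of the IXS experiment: phase scenarios with known
# dispersion truth, Poisson counting noise, seeded dataset generation.

#' Define a simulated phase scenario
#'
#' The study conditions emulated by the simulator: 18 momentum transfers
#' spanning 2.47-27.29 nm^-1, 97 energy points per scan over +/- 15 meV,
#' a Pseudo-Voigt resolution of 1.7 meV FWHM, Poisson counting noise, one
#' longitudinal and one transverse acoustic branch. Built-in scenarios carry
#' the measured values of the two lamellar phases of DPPC:
#' `gel_20C` (v_L = 2532 m/s, v_T = 582 m/s, Q_min = 15.4 nm^-1, no
#' transverse gap) and `fluid_45C` (v_L = 2241 m/s, v_T = 582 m/s,
#' Q_min = 14.2 nm^-1, transverse branch suppressed below 5 nm^-1).
#'
#' @param name `"gel_20C"`, `"fluid_45C"` or `"custom"`.
#' @param ... For `"custom"` (or to override a built-in): any of
#'   `temperature_C`, `v_long`, `v_trans` (m/s), `q_zone_boundary` (nm^-1),
#'   `gap_edge` (nm^-1 or `NA` for none), `omega_min_long`,
#'   `omega_min_trans` (dispersion-minimum depth, meV), `linear_fraction`
#'   (fraction of `q_zone_boundary` up to which the branch is exactly
#'   linear), `gamma_long`,
#'   `gamma_trans` (length-2: `Gamma(q) = g0 + g1*q`, meV),
#'   `strength_long`, `strength_trans` (see Details), `peak_counts`,
#'   `background_counts`, `rf`, `grid`, `q_list`.
#' @details The longitudinal integrated strength is constant over the
#'   measured Q range, `I_L = strength_long * peak_counts` counts meV (the
#'   Q^2 one-phonon factor and the 1/omega^2 thermal amplitude of an
#'   acoustic mode roughly cancel). The transverse strength carries an
#'   equipartition-flavoured boost saturating at a 2 meV scale,
#'   `I_T = strength_trans * peak_counts * (1 + (2 meV/omega_T)^2)`, so
#'   low-energy shear modes are thermally intense. Both are sized so
#'   inelastic features carry a few percent of the elastic intensity, as in
#'   the measured spectra.
#' @return An object of class `phase_scenario`.
#' @export
#' @examples
#' sc <- phase_scenario("fluid_45C")
#' true_dispersion(sc, "transverse", c(3, 6, 12))
phase_scenario <- function(name = c("gel_20C", "fluid_45C", "custom"), ...) {
  name <- match.arg(name)
  base <- list(
    name = name,
    temperature_C = 20,
    v_long = 2532, v_trans = 582,
    q_zone_boundary = 15.4,
    gap_edge = NA_real_,
    omega_min_long = 2.0, omega_min_trans = 1.0,
    linear_fraction = 0.45,
    gamma_long = c(0.4, 0.12), gamma_trans = c(1.0, 0.05),
    strength_long = 0.06, strength_trans = 0.06,
    peak_counts = 5000, background_counts = 20,
    rf = resolution_function(1.7, 0.5),
    grid = seq(-15, 15, length.out = 97),
    q_list = seq(2.47, 27.29, length.out = 18))
  if (name == "fluid_45C") {
    base$temperature_C <- 45
    base$v_long <- 2241
    base$q_zone_boundary <- 14.2
    base$gap_edge <- 5
    base$gamma_long <- c(0.8, 0.18)
    base$gamma_trans <- c(0.8, 0.15)
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown) > 0L) {
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base[names(overrides)] <- overrides
  with(base, {
    stopifnot(v_long > 0, v_trans > 0, q_zone_boundary > 0, peak_counts > 0,
              background_counts >= 0, all(diff(q_list) > 0), all(q_list > 0))
  })
  check_energy_grid(base$grid)
  stopifnot(inherits(base$rf, "ixs_rf"))
  structure(base, class = "phase_scenario")
}

#' @export
print.phase_scenario <- function(x, ...) {
  cat(sprintf("<phase_scenario> %s: T = %g degC, v_L = %g, v_T = %g m/s, Q_min = %g nm^-1\n",
              x$name, x$temperature_C, x$v_long, x$v_trans, x$q_zone_boundary))
  cat(sprintf("  gap edge: %s; %d Q values, %d energy points, peak %g counts\n",
              if (is.na(x$gap_edge)) "none" else paste0(x$gap_edge, " nm^-1"),
              length(x$q_list), length(x$grid), x$peak_counts))
  invisible(x)
}

#' True dispersion relation of a simulated scenario
#'
#' An acoustic parameterization chosen as the minimal shape with (i) the
#' branch sound speed as its exact low-Q slope over a genuinely linear
#' regime and (ii) a local minimum of depth `omega_min` exactly at the zone
#' boundary: `omega(q) = S*q` (with `S = v / 1519.2674` meV nm) up to
#' `q_c = linear_fraction * q_zone_boundary`, then a C1 cubic Hermite
#' segment from `(q_c, S*q_c)` (slope `S`) to `(q_zb, omega_min)` (slope 0),
#' evenly reflected about the zone boundary beyond it. The damping is
#' linear, `Gamma(q) = g0 + g1*q`. This is a simulator convention, not a
#' physical model of the lipid. Transverse modes are absent below the
#' scenario's `gap_edge`.
#'
#' @param scenario A [phase_scenario()].
#' @param branch `"longitudinal"` or `"transverse"`.
#' @param q Momentum transfer(s) in nm^-1 (> 0). Vectorized.
#' @return A tibble: `q`, `branch`, `present`, `omega` (meV), `gamma` (meV);
#'   `omega`/`gamma` are `NA` where the mode is absent.
#' @export
true_dispersion <- function(scenario, branch = c("longitudinal", "transverse"),
                            q) {
  stopifnot(inherits(scenario, "phase_scenario"))
  branch <- match.arg(branch)
  if (any(q <= 0)) stop("`q` must be positive.", call. = FALSE)
  v <- if (branch == "longitudinal") scenario$v_long else scenario$v_trans
  wmin <- if (branch == "longitudinal") scenario$omega_min_long else scenario$omega_min_trans
  g <- if (branch == "longitudinal") scenario$gamma_long else scenario$gamma_trans
  qzb <- scenario$q_zone_boundary
  s <- v / SLOPE_TO_SPEED
  qc <- scenario$linear_fraction * qzb
  # fold into [0, qzb] by even reflection about the zone boundary
  qm <- q %% (2 * qzb)
  qe <- ifelse(qm <= qzb, qm, 2 * qzb - qm)
  h <- qzb - qc
  t <- pmin(pmax((qe - qc) / h, 0), 1)
  hermite <- (2 * t^3 - 3 * t^2 + 1) * (s * qc) +
    (t^3 - 2 * t^2 + t) * h * s +
    (-2 * t^3 + 3 * t^2) * wmin
  omega <- ifelse(qe <= qc, s * qe, hermite)
  gamma <- g[1] + g[2] * q
  present <- rep(TRUE, length(q))
  if (branch == "transverse" && !is.na(scenario$gap_edge)) {
    present <- q >= scenario$gap_edge
  }
  tibble::tibble(q = q, branch = branch, present = present,
                 omega = ifelse(present, omega, NA_real_),
                 gamma = ifelse(present, gamma, NA_real_))
}

# True model parameters of a scenario at one Q (modes only where present).
scenario_params <- function(scenario, q) {
  temperature <- celsius_to_kelvin(scenario$temperature_C)
  modes <- list()
  strengths <- c(longitudinal = scenario$strength_long,
                 transverse = scenario$strength_trans)
  for (br in c("transverse", "longitudinal")) {
    tr <- true_dispersion(scenario, br, q)
    if (tr$present) {
      intensity <- strengths[[br]] * scenario$peak_counts
      if (br == "transverse") {
        # equipartition-flavoured boost: low-energy shear modes carry the
        # thermal amplitude ~ kT/omega^2, saturating at a 2 meV scale
        intensity <- intensity * (1 + (2 / tr$omega)^2)
      } else {
        # density modes couple through S(Q), which peaks at the chain
        # correlation peak, i.e. at the zone boundary (width ~ 1.5 nm^-1)
        intensity <- intensity *
          (1 + 2 * exp(-(q - scenario$q_zone_boundary)^2 / (2 * 1.5^2)))
      }
      modes <- c(modes, list(dho_mode(tr$omega, tr$gamma, intensity, label = br)))
    }
  }
  # elastic amplitude set so the expected count rate at omega = 0 matches
  # peak_counts once background and inelastic contributions are included
  inelastic0 <- if (length(modes) > 0L) {
    p0 <- spectral_params(0, 0, modes, temperature)
    model0 <- evaluate_model(p0, scenario$grid, scenario$rf)
    model0[which.min(abs(scenario$grid))]
  } else 0
  pv0 <- pseudo_voigt(0, scenario$rf)
  a0 <- (scenario$peak_counts - scenario$background_counts - inelastic0) / pv0
  a0 <- max(a0, 0.05 * scenario$peak_counts / pv0)
  spectral_params(a0, scenario$background_counts, modes, temperature)
}

#' Simulate one IXS spectrum
#'
#' Evaluates the full spectral model with the scenario's true modes at the
#' given Q, draws Poisson counts per energy point, and sets the 1-s.d.
#' errors to `sqrt(max(counts, 1))`. Deterministic for a given seed.
#'
#' @param scenario A [phase_scenario()].
#' @param q Momentum transfer in nm^-1.
#' @param seed Integer seed for the Poisson draw.
#' @return An [ixs_spectrum()] with attribute `truth` (the tibble of true
#'   modes at this Q) and `expected` (noise-free model counts).
#' @export
generate_spectrum <- function(scenario, q, seed = 1L) {
  stopifnot(inherits(scenario, "phase_scenario"))
  params <- scenario_params(scenario, q)
  expected <- evaluate_model(params, scenario$grid, scenario$rf)
  counts <- withr::with_seed(as.integer(seed), stats::rpois(length(expected), expected))
  sp <- ixs_spectrum(scenario$grid, counts, sqrt(pmax(counts, 1)), q = q,
                     temperature_C = scenario$temperature_C, rf = scenario$rf)
  attr(sp, "truth") <- dplyr::bind_rows(
    true_dispersion(scenario, "longitudinal", q),
    true_dispersion(scenario, "transverse", q))
  attr(sp, "expected") <- expected
  sp
}

#' Simulate a full dataset (one spectrum per Q) with a truth manifest
#'
#' Draws one spectrum per Q in the scenario's `q_list`, each with a
#' deterministic sub-seed derived from the master seed, and records the
#' generator truth (per-Q omega, Gamma, presence, and the scenario
#' constants) in a manifest for recovery tests.
#'
#' @param scenario A [phase_scenario()].
#' @param seed Integer master seed.
#' @return A list of class `ixs_dataset`: `spectra` (list of
#'   [ixs_spectrum()]), `manifest` (tibble with one row per Q and branch),
#'   `scenario`, `seed`.
#' @export
generate_dataset <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "phase_scenario"))
  spectra <- vector("list", length(scenario$q_list))
  manifest <- vector("list", length(scenario$q_list))
  for (i in seq_along(scenario$q_list)) {
    q <- scenario$q_list[i]
    sub_seed <- derive_seed(seed, i)
    spectra[[i]] <- generate_spectrum(scenario, q, seed = sub_seed)
    truth <- attr(spectra[[i]], "truth")
    truth$sub_seed <- sub_seed
    manifest[[i]] <- truth
  }
  structure(list(spectra = spectra,
                 manifest = dplyr::bind_rows(manifest),
                 scenario = scenario,
                 seed = as.integer(seed)),
            class = "ixs_dataset")
}

#' @export
print.ixs_dataset <- function(x, ...) {
  cat(sprintf("<ixs_dataset> %s: %d spectra, seed %d\n",
              x$scenario$name, length(x$spectra), x$seed))
  invisible(x)
}
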