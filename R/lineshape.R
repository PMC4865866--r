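# Forward spectral model: Pseudo-Voigt resolution function, detailed balance,
# DHO phonon profiles, resolution convolution, and total model evaluation.

#' Instrument resolution function (Pseudo-Voigt)
#'
#' Describes the IXS spectrometer's response to a purely elastic scatterer as
#' a Pseudo-Voigt profile: a linear mix of a Lorentzian and a Gaussian that
#' share the same full width at half maximum.
#'
#' @param fwhm Full width at half maximum in meV. Must be positive.
#' @param eta Dimensionless mixing parameter in `[0, 1]`: the fraction of
#'   Lorentzian character (`eta = 1` is a pure Lorentzian, `eta = 0` a pure
#'   Gaussian). Defaults to 0.5.
#' @return An object of class `ixs_rf` (a named list with `fwhm` and `eta`).
#' @export
#' @examples
#' rf <- resolution_function(fwhm = 1.7, eta = 0.5)
#' pseudo_voigt(seq(-5, 5, by = 0.5), rf)
resolution_function <- function(fwhm, eta = 0.5) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || !is.finite(fwhm) || fwhm <= 0) {
    stop("`fwhm` must be a single positive number (meV).", call. = FALSE)
  }
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta < 0 || eta > 1) {
    stop("`eta` must be a single number in [0, 1].", call. = FALSE)
  }
  structure(list(fwhm = fwhm, eta = eta), class = "ixs_rf")
}

#' @export
print.ixs_rf <- function(x, ...) {
  cat(sprintf("<ixs_rf> Pseudo-Voigt, FWHM = %g meV, eta = %g\n", x$fwhm, x$eta))
  invisible(x)
}

#' Evaluate the Pseudo-Voigt resolution profile
#'
#' `eta * L(omega) + (1 - eta) * G(omega)` where `L` and `G` are unit-area
#' Lorentzian and Gaussian densities with the same FWHM. The profile is
#' symmetric about zero and has unit area on an infinite domain.
#'
#' @param omega Energy transfer(s) in meV.
#' @param rf An [resolution_function()] object.
#' @return Density values in meV^-1, same length as `omega`.
#' @export
pseudo_voigt <- function(omega, rf) {
  stopifnot(inherits(rf, "ixs_rf"))
  hwhm <- rf$fwhm / 2
  lor <- (hwhm / pi) / (omega^2 + hwhm^2)
  sigma <- rf$fwhm / (2 * sqrt(2 * log(2)))
  gau <- stats::dnorm(omega, mean = 0, sd = sigma)
  rf$eta * lor + (1 - rf$eta) * gau
}

#' Quantum detailed-balance weight
#'
#' The weight `B(omega, T) = x / (1 - exp(-x))` with `x = hbar*omega / kB*T`
#' (energies in meV). It satisfies `B(omega) / B(-omega) = exp(x)`, the
#' Stokes/anti-Stokes asymmetry between phonon creation and annihilation, and
#' `B(0, T) = 1` by continuous extension. This first-moment-preserving
#' convention is applied to every inelastic (DHO) term.
#'
#' @param omega Energy transfer(s) in meV.
#' @param temperature Temperature in kelvin (> 0). `Inf` gives the classical
#'   limit `B == 1`.
#' @return Dimensionless weights, same length as `omega`.
#' @export
#' @examples
#' detailed_balance_factor(c(-2, 0, 2), 293.15)
detailed_balance_factor <- function(omega, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number (kelvin).", call. = FALSE)
  }
  if (is.infinite(temperature)) {
    return(rep(1, length(omega)))
  }
  x <- omega / (KB_MEV_PER_K * temperature)
  out <- x / (1 - exp(-x))
  # x/(1 - exp(-x)) -> 1 as x -> 0; the series keeps tiny |x| exact
  small <- abs(x) < 1e-8
  out[small] <- 1 + x[small] / 2
  out
}

#' A damped-harmonic-oscillator phonon mode
#'
#' One inelastic excitation with energy `Omega`, damping width `Gamma` and
#' integrated strength `I`, the three free parameters per mode of the
#' spectral model.
#'
#' @param omega0 Excitation energy Omega(Q) in meV (>= 0).
#' @param gamma Damping width Gamma(Q) in meV (> 0).
#' @param intensity Integrated mode strength I(Q) in counts meV (>= 0).
#' @param label Branch label: `"longitudinal"`, `"transverse"` or
#'   `"unassigned"`.
#' @return An object of class `ixs_dho_mode`.
#' @export
dho_mode <- function(omega0, gamma, intensity,
                     label = c("unassigned", "longitudinal", "transverse")) {
  label <- match.arg(label)
  if (!is.numeric(omega0) || length(omega0) != 1L || is.na(omega0) || omega0 < 0) {
    stop("`omega0` must be a single non-negative number (meV).", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma <= 0) {
    stop("`gamma` must be a single positive number (meV).", call. = FALSE)
  }
  if (!is.numeric(intensity) || length(intensity) != 1L || is.na(intensity) ||
      intensity < 0) {
    stop("`intensity` must be a single non-negative number (counts meV).",
         call. = FALSE)
  }
  structure(list(omega0 = omega0, gamma = gamma, intensity = intensity,
                 label = label),
            class = "ixs_dho_mode")
}

# Classical DHO spectral kernel: even in omega, unit area on (-Inf, Inf) for
# any Omega, Gamma > 0, with peaks near +/-Omega when underdamped.
dho_kernel <- function(omega, omega0, gamma) {
  if (omega0 <= 0) {
    return(rep(0, length(omega)))
  }
  (gamma * omega0^2 / pi) / ((omega^2 - omega0^2)^2 + (gamma * omega)^2)
}

#' DHO mode spectral density with detailed balance
#'
#' The inelastic contribution of one phonon mode before resolution
#' convolution:
#' `I * B(omega, T) * (1/pi) * Gamma * Omega^2 / ((omega^2 - Omega^2)^2 + (Gamma*omega)^2)`.
#' The classical kernel is even in `omega` and normalized to unit area, so
#' `intensity` is the integrated strength in the classical limit
#' (`temperature = Inf`).
#'
#' @param omega Energy transfer(s) in meV.
#' @param mode An [dho_mode()] object.
#' @param temperature Temperature in kelvin for the detailed-balance weight;
#'   `Inf` gives the classical (symmetric) profile.
#' @return Spectral density in counts meV^-1, same length as `omega`.
#' @export
dho_profile <- function(omega, mode, temperature) {
  stopifnot(inherits(mode, "ixs_dho_mode"))
  mode$intensity * detailed_balance_factor(omega, temperature) *
    dho_kernel(omega, mode$omega0, mode$gamma)
}

#' Spectral model parameters
#'
#' The full parameter set of the fit model: elastic amplitude `S(Q,0)` (the
#' central peak whose shape equals the resolution function), a flat
#' background, up to two DHO modes, and the temperature fixing the
#' detailed-balance weight.
#'
#' @param elastic_amplitude Amplitude of the elastic line in counts (>= 0).
#' @param background Flat background level in counts (>= 0).
#' @param modes List of 0-2 [dho_mode()] objects.
#' @param temperature Sample temperature in kelvin (> 0).
#' @return An object of class `ixs_params`.
#' @export
spectral_params <- function(elastic_amplitude, background, modes = list(),
                            temperature) {
  if (!is.numeric(elastic_amplitude) || length(elastic_amplitude) != 1L ||
      is.na(elastic_amplitude) || elastic_amplitude < 0) {
    stop("`elastic_amplitude` must be a single non-negative number.", call. = FALSE)
  }
  if (!is.numeric(background) || length(background) != 1L ||
      is.na(background) || background < 0) {
    stop("`background` must be a single non-negative number.", call. = FALSE)
  }
  if (!is.list(modes) || length(modes) > 2L ||
      !all(vapply(modes, inherits, logical(1), "ixs_dho_mode"))) {
    stop("`modes` must be a list of 0 to 2 `dho_mode` objects.", call. = FALSE)
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number (kelvin).", call. = FALSE)
  }
  structure(list(elastic_amplitude = elastic_amplitude, background = background,
                 modes = modes, temperature = temperature),
            class = "ixs_params")
}

#' @export
print.ixs_params <- function(x, ...) {
  cat(sprintf("<ixs_params> S(Q,0) = %.4g, background = %.4g, T = %.4g K, %d mode(s)\n",
              x$elastic_amplitude, x$background, x$temperature, length(x$modes)))
  for (m in x$modes) {
    cat(sprintf("  %-12s Omega = %.4g meV, Gamma = %.4g meV, I = %.4g\n",
                m$label, m$omega0, m$gamma, m$intensity))
  }
  invisible(x)
}

check_energy_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 3L || anyNA(grid)) {
    stop("energy grid must be numeric with at least 3 finite points.",
         call. = FALSE)
  }
  if (any(diff(grid) <= 0)) {
    stop("energy grid must be strictly increasing.", call. = FALSE)
  }
  invisible(grid)
}

#' Convolve a spectral density with the resolution function
#'
#' Discrete convolution `(model x RF)(omega)` sampled on a (possibly
#' irregular) measurement grid. The density is evaluated on an internal
#' uniform fine grid (step `min(grid spacing)/2`, capped at `fwhm/10`) padded
#' by `5 * fwhm` beyond both grid ends, convolved with a discrete RF kernel
#' (evaluated to `+/- 60 * fwhm` and renormalized to unit mass so the
#' zeroth moment of a well-padded density is conserved), and linearly
#' interpolated back to the measurement grid.
#'
#' @param model_density A function of omega (meV) returning spectral density.
#' @param rf An [resolution_function()] object.
#' @param grid Strictly increasing energy grid in meV (length >= 3).
#' @return Convolved values on `grid`.
#' @export
convolve_with_rf <- function(model_density, rf, grid) {
  stopifnot(inherits(rf, "ixs_rf"), is.function(model_density))
  cv <- make_convolver(rf, grid)
  cv$smear(model_density(cv$fine))
}

# Precomputed convolution machinery for repeated evaluation on one grid:
# fine grid, unit-mass discrete RF kernel, and the smear-and-interpolate map.
make_convolver <- function(rf, grid) {
  check_energy_grid(grid)
  step <- min(min(diff(grid)) / 2, rf$fwhm / 10)
  pad <- 5 * rf$fwhm
  lo <- min(grid) - pad
  hi <- max(grid) + pad
  n_fine <- ceiling((hi - lo) / step) + 1L
  fine <- lo + step * (seq_len(n_fine) - 1L)
  nk <- ceiling(60 * rf$fwhm / step)
  kern <- pseudo_voigt((-nk:nk) * step, rf)
  kern <- kern / sum(kern)  # unit discrete mass: conserves counts exactly
  list(
    fine = fine,
    smear = function(dens) {
      if (anyNA(dens)) {
        stop("model density returned NA on the fine grid.", call. = FALSE)
      }
      conv <- stats::convolve(dens, rev(kern), type = "open")
      stats::approx(fine, conv[(nk + 1L):(nk + n_fine)], xout = grid)$y
    })
}

#' Evaluate the full spectral model on a grid
#'
#' `background + S(Q,0) * RF(omega) + sum over modes of (DHO x RF)(omega)`.
#' The elastic term is a delta function convolved with the resolution
#' function, i.e. the RF shape itself with a free amplitude; each DHO term
#' carries the detailed-balance weight at the model temperature before
#' convolution.
#'
#' @param params An [spectral_params()] object.
#' @param grid Strictly increasing energy grid in meV.
#' @param rf An [resolution_function()] object.
#' @return Model counts on `grid`.
#' @export
evaluate_model <- function(params, grid, rf) {
  make_model_evaluator(grid, rf)(params)
}

# Factory caching the per-grid pieces (elastic shape, convolver) so that
# repeated evaluation during fitting only recomputes the DHO densities.
make_model_evaluator <- function(grid, rf) {
  stopifnot(inherits(rf, "ixs_rf"))
  check_energy_grid(grid)
  pv_grid <- pseudo_voigt(grid, rf)
  cv <- make_convolver(rf, grid)
  function(params) {
    stopifnot(inherits(params, "ixs_params"))
    out <- params$background + params$elastic_amplitude * pv_grid
    if (length(params$modes) > 0L) {
      dens <- rep(0, length(cv$fine))
      for (m in params$modes) {
        dens <- dens + dho_profile(cv$fine, m, params$temperature)
      }
      out <- out + cv$smear(dens)
    }
    out
  }
}
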