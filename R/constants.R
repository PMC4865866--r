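# Physical constants in the package's meV / nm / K unit system.

# Boltzmann constant, meV per kelvin
KB_MEV_PER_K <- 8.617333262e-2

# Reduced Planck constant, meV * s
HBAR_MEV_S <- 6.582119569e-13

# Conversion of a linear acoustic dispersion slope to a speed:
# v [m/s] = slope [meV * nm] * SLOPE_TO_SPEED.
# Derivation: v = (E/hbar)/Q with E in meV and Q in nm^-1, i.e.
# 1 meV / (hbar * 1 nm^-1) = 1e-3 * e / (hbar_J * 1e9) = 1519.2674 m/s.
SLOPE_TO_SPEED <- 1e-3 * 1.602176634e-19 / (1.054571817e-34 * 1e9)

#' Physical constants used by the package
#'
#' Returns the constants table used throughout: the Boltzmann constant in
#' meV/K, the reduced Planck constant in meV s, and the conversion factor
#' from a dispersion slope in meV nm to a sound speed in m/s.
#'
#' @return A tibble with columns `constant`, `value`, `unit`.
#' @export
#' @examples
#' ixs_constants()
ixs_constants <- function() {
  tibble::tibble(
    constant = c("k_B", "hbar", "slope_to_speed"),
    value = c(KB_MEV_PER_K, HBAR_MEV_S, SLOPE_TO_SPEED),
    unit = c("meV/K", "meV s", "(m/s) per (meV nm)")
  )
}

celsius_to_kelvin <- function(temperature_C) temperature_C + 273.15
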