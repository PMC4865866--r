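# The spectrum container: a tibble of (energy, intensity, error) with the
# scan metadata (Q, temperature, resolution) carried as attributes.

#' Construct an IXS spectrum
#'
#' One measured or simulated scan at fixed momentum transfer Q: a tibble with
#' columns `energy` (meV), `intensity` (counts) and `error` (1 s.d. counts),
#' plus metadata attributes `q` (nm^-1), `temperature_C` and the resolution
#' function.
#'
#' @param energy Strictly increasing energy transfers in meV (length >= 3,
#'   spanning both signs for any grid used in fitting).
#' @param intensity Counts per point.
#' @param error 1-s.d. counting errors per point (all > 0).
#' @param q Momentum transfer in nm^-1 (> 0).
#' @param temperature_C Sample temperature in degrees Celsius.
#' @param rf An [resolution_function()] object.
#' @return A tibble of class `ixs_spectrum`.
#' @export
ixs_spectrum <- function(energy, intensity, error, q, temperature_C, rf) {
  check_energy_grid(energy)
  if (length(intensity) != length(energy) || length(error) != length(energy)) {
    stop("`energy`, `intensity` and `error` must have equal lengths.",
         call. = FALSE)
  }
  if (anyNA(intensity) || anyNA(error)) {
    stop("`intensity` and `error` must not contain NA.", call. = FALSE)
  }
  if (any(error <= 0)) {
    stop("`error` must be positive everywhere.", call. = FALSE)
  }
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0) {
    stop("`q` must be a single positive number (nm^-1).", call. = FALSE)
  }
  if (!is.numeric(temperature_C) || length(temperature_C) != 1L ||
      is.na(temperature_C)) {
    stop("`temperature_C` must be a single number.", call. = FALSE)
  }
  stopifnot(inherits(rf, "ixs_rf"))
  out <- tibble::tibble(energy = as.numeric(energy),
                        intensity = as.numeric(intensity),
                        error = as.numeric(error))
  attr(out, "q") <- as.numeric(q)
  attr(out, "temperature_C") <- as.numeric(temperature_C)
  attr(out, "rf") <- rf
  class(out) <- c("ixs_spectrum", class(out))
  out
}

#' @export
print.ixs_spectrum <- function(x, ...) {
  cat(sprintf("<ixs_spectrum> Q = %g nm^-1, T = %g degC, %d points, RF FWHM = %g meV\n",
              attr(x, "q"), attr(x, "temperature_C"), nrow(x), attr(x, "rf")$fwhm))
  NextMethod()
}

spectrum_q <- function(spectrum) attr(spectrum, "q")
spectrum_temperature_K <- function(spectrum) {
  celsius_to_kelvin(attr(spectrum, "temperature_C"))
}
spectrum_rf <- function(spectrum) attr(spectrum, "rf")

check_spectrum <- function(spectrum) {
  if (!inherits(spectrum, "ixs_spectrum")) {
    stop("`spectrum` must be an `ixs_spectrum` (see `ixs_spectrum()`).",
         call. = FALSE)
  }
  invisible(spectrum)
}
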