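# Independent oracles used by the tests: straightforward direct-quadrature
# implementations, deliberately kept separate from the package's FFT path.

# Direct trapezoid convolution of a density with the Pseudo-Voigt profile,
# evaluated point by point (O(n^2); independent of stats::convolve).
oracle_convolve <- function(density_fn, rf, grid, pad_fwhm = 8, step_frac = 20) {
  step <- rf$fwhm / step_frac
  u <- seq(min(grid) - pad_fwhm * rf$fwhm, max(grid) + pad_fwhm * rf$fwhm,
           by = step)
  du <- density_fn(u)
  vapply(grid, function(w) {
    integrand <- du * pseudo_voigt(w - u, rf)
    sum((integrand[-1] + integrand[-length(integrand)]) / 2) * step
  }, numeric(1))
}

# Direct evaluation of the full spectral model through the oracle convolution.
oracle_model <- function(params, grid, rf) {
  out <- params$background + params$elastic_amplitude * pseudo_voigt(grid, rf)
  if (length(params$modes) > 0L) {
    dens <- function(w) {
      total <- rep(0, length(w))
      for (m in params$modes) total <- total + dho_profile(w, m, params$temperature)
      total
    }
    out <- out + oracle_convolve(dens, rf, grid)
  }
  out
}

standard_grid <- function() seq(-15, 15, length.out = 97)

# A quick noise-free spectrum built from known parameters.
noise_free_spectrum <- function(params, q = 5, temperature_C = 45,
                                rf = resolution_function(1.7, 0.5),
                                grid = standard_grid()) {
  counts <- evaluate_model(params, grid, rf)
  ixs_spectrum(grid, counts, sqrt(pmax(counts, 1)), q = q,
               temperature_C = temperature_C, rf = rf)
}
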