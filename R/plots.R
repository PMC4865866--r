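# ggplot2 visualisations of fits, dispersion branches and damping ratios.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted spectrum with its model components
#'
#' Data with 1-s.d. error bars, total model, elastic line and per-mode DHO
#' contributions (after resolution convolution).
#'
#' @param object An `ixs_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ixs_fit
#' @export
autoplot.ixs_fit <- function(object, ...) {
  sp <- object$spectrum
  rf <- spectrum_rf(sp)
  grid <- sp$energy
  p <- object$params
  elastic <- p$background + p$elastic_amplitude * pseudo_voigt(grid, rf)
  comps <- tibble::tibble(energy = grid, counts = elastic,
                          component = "elastic + background")
  for (m in p$modes) {
    one <- spectral_params(0, 0, list(m), p$temperature)
    comps <- dplyr::bind_rows(comps, tibble::tibble(
      energy = grid, counts = evaluate_model(one, grid, rf),
      component = paste0(m$label, " DHO")))
  }
  total <- tibble::tibble(energy = grid,
                          counts = evaluate_model(p, grid, rf),
                          component = "total fit")
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$energy)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$intensity,
                                          ymin = .data$intensity - .data$error,
                                          ymax = .data$intensity + .data$error),
                             size = 0.15, colour = "grey30") +
    ggplot2::geom_line(data = comps,
                       ggplot2::aes(y = .data$counts, colour = .data$component),
                       linetype = "dashed") +
    ggplot2::geom_line(data = total,
                       ggplot2::aes(y = .data$counts, colour = .data$component),
                       linewidth = 0.8) +
    ggplot2::labs(x = "energy transfer (meV)", y = "intensity (counts)",
                  colour = NULL,
                  title = sprintf("Q = %.2f nm⁻¹, reduced χ² = %.2f",
                                  object$q, object$reduced_chi2)) +
    ggplot2::theme_minimal()
}

#' Plot assembled dispersion branches
#'
#' omega(Q) per branch with 1-sigma error bars; absent transverse points
#' (the phononic gap) simply do not appear.
#'
#' @param object An `ixs_branches` table from [assemble_branches()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ixs_branches
#' @export
autoplot.ixs_branches <- function(object, ...) {
  b <- object[object$present & !is.na(object$omega), , drop = FALSE]
  ggplot2::ggplot(b, ggplot2::aes(x = .data$q, y = .data$omega,
                                  colour = .data$branch)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$omega - .data$omega_err,
                                          ymax = .data$omega + .data$omega_err)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "Q (nm⁻¹)", y = "ħω (meV)",
                  colour = "branch") +
    ggplot2::theme_minimal()
}

#' Plot damping ratios R = omega/Gamma along the branches
#'
#' @param branches A branch table processed by [damping_ratio()].
#' @return A ggplot with the R = 1 over/underdamped crossover marked.
#' @export
plot_damping_ratio <- function(branches) {
  stopifnot("R" %in% names(branches))
  b <- branches[branches$present & !is.na(branches$R), , drop = FALSE]
  ggplot2::ggplot(b, ggplot2::aes(x = .data$q, y = .data$R,
                                  colour = .data$branch)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$R - .data$R_err,
                                          ymax = .data$R + .data$R_err)) +
    ggplot2::labs(x = "Q (nm⁻¹)", y = "R = ω/Γ",
                  colour = "branch") +
    ggplot2::theme_minimal()
}
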