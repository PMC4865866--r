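Package: ixsphonon
Title: Phonon Dispersion Analysis of Inelastic X-Ray Scattering Spectra from Lipid Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits inelastic X-ray scattering (IXS) spectra S(Q,w) of lipid
    multilayers with an elastic line plus damped-harmonic-oscillator (DHO)
    phonon modes convolved with a Pseudo-Voigt instrument resolution function,
    selects the number of propagating modes per spectrum by reduced chi-squared
    and a symmetric-residual diagnostic, assembles longitudinal and transverse
    acoustic dispersion branches omega(Q), and derives sound speeds, the
    quasi-Brillouin-zone boundary, the area per lipid, damping ratios, and the
    low-Q transverse phononic band gap with the associated dynamic cluster
    size. Includes a seeded forward simulator of the experiment (Poisson
    counting noise on a 97-point energy grid across 18 momentum transfers) so
    the full pipeline is testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
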