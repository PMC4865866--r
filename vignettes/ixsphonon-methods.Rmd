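---
title: "Modelling collective lipid dynamics from inelastic X-ray scattering spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling collective lipid dynamics from inelastic X-ray scattering spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ixsphonon)
```

## The problem

Inelastic X-ray scattering (IXS) measures the dynamic structure factor
$S(Q,\omega)$ of a sample: how density fluctuations at momentum transfer $Q$
distribute over energy transfers $\hbar\omega$. In an oriented phospholipid
multilayer probed in the membrane plane, the picosecond collective motions of
the acyl chains appear as weak inelastic "shoulders" on either side of a
dominant elastic line. Two acoustic mode families matter: longitudinal
(compressive) phonons, routinely seen in lipids, and in-plane transverse
(shear) phonons, which only propagate where the local chain packing supports
shear restoring forces. In the fluid ($L_\alpha$) phase the transverse branch
disappears below a cutoff $Q_\mathrm{gap}$ — a phononic band gap whose length
scale $d_\mathrm{gap} = 2\pi/Q_\mathrm{gap}$ measures the size of transient,
solid-like lipid clusters.

`ixsphonon` implements the full analysis chain for such an experiment:
spectral fitting, per-spectrum model selection, dispersion assembly, and the
derived physical observables, together with a seeded forward simulator so
that every stage can be exercised and calibrated without measured data.

## The spectral model

A measured spectrum at fixed $Q$ is modelled as

$$
I(\omega) = b \;+\; S(Q,0)\,R(\omega) \;+\;
\sum_{j=1}^{n} \big[ I_j\, B(\omega,T)\, D_j(\omega) \big] \otimes R(\omega),
\qquad n \in \{0,1,2\},
$$

with

* $R(\omega)$ the instrument resolution function, a Pseudo-Voigt profile
  $\eta L(\omega) + (1-\eta) G(\omega)$ (unit-area Lorentzian and Gaussian
  sharing one FWHM, default 1.7 meV, $\eta = 0.5$). The elastic line — static
  structure plus all quasi-elastic motion unresolved at this resolution — is
  a $\delta(\omega)$ convolved with $R$, i.e. $R$ itself with the single free
  amplitude $S(Q,0)$.
* $D_j$ the classical damped-harmonic-oscillator (DHO) kernel
  $$D(\omega) = \frac{1}{\pi}\,
  \frac{\Gamma\,\Omega^2}{(\omega^2-\Omega^2)^2 + (\Gamma\omega)^2},$$
  even in $\omega$ and unit-area for any $\Omega,\Gamma>0$, so $I_j$ is the
  integrated mode strength. For an underdamped mode the spectral peaks sit
  near $\pm\sqrt{\Omega^2 - \Gamma^2/2}$. The kernel sits behind a single
  internal function, so an alternative DHO convention is a one-line change.
* $B(\omega,T) = x/(1-e^{-x})$, $x = \hbar\omega/k_BT$, the
  first-moment-preserving detailed-balance weight; it makes phonon creation
  ($\omega>0$) stronger than annihilation by $e^{x}$ and equals 1 at
  $\omega = 0$. The temperature is the nominal sample temperature in kelvin,
  not a fit parameter.
* $b$ a flat background.

Free parameters: $S(Q,0)$, $b$, and $(\Omega_j, \Gamma_j, I_j)$ per mode —
$2 + 3n$ in total.

### Numerical convolution

The DHO terms are evaluated on an internal uniform grid (step
$\min(\Delta\omega_\mathrm{grid})/2$, capped at FWHM/10) padded by 5 FWHM
beyond the measurement range, convolved by FFT with a discrete resolution
kernel, and linearly interpolated back to the (possibly irregular)
measurement grid. The kernel is evaluated out to $\pm 60$ FWHM and
renormalised to unit discrete mass: the Lorentzian half of a Pseudo-Voigt
keeps about 6% of its mass beyond $\pm 5$ FWHM, and truncating there would
visibly violate count conservation. With the wide, renormalised kernel the
discrete zeroth moment is conserved exactly and the residual shape bias is
at the 0.5% level (verified against a direct quadrature oracle in the test
suite).

## Fitting and uncertainties

Fits minimise $\sum_i [(y_i - m_i)/\sigma_i]^2$ with bounded
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`). All parameters are
bounded below by zero; mode widths additionally by
$\min(\mathrm{FWHM}/8, 0.25)$ meV, because a DHO much narrower than the
resolution is unidentifiable after convolution and an unbounded
$\Gamma \to 0$ lets a near-delta satellite pair latch onto counting noise.
$\Omega$ is capped at the largest measured $|\omega|$.

Initialisation is data-driven: $S(Q,0)$ from the spectrum maximum after
subtracting a background estimated from the outer 10% of energy points; the
mode energy from the strongest smoothed residual shoulder of an elastic-only
fit (fall-back 8 meV; in two-mode fits the first mode starts at the 2 meV
transverse candidate); widths start at 2 meV; intensities from the local
excess above the elastic-only model. Each fit is restarted five times with
the starting $\Omega$ and $\Gamma$ perturbed log-uniformly in
$[\times 0.5, \times 2]$, keeping the best sum of squares; the restart
stream is seeded, so identical spectrum and seed give bit-identical results.

Parameter errors are 1 s.d. values from the covariance of the linearised
weighted problem at the optimum, $(J^\top J)^{-1}$. On ensembles of
simulated spectra at the default statistics the nominal 1$\sigma$ intervals
for $\Omega$ cover the truth in roughly two thirds of replicates — the
Gaussian approximation is adequate but not exact, which is why the test
suite asserts a 60–80% band rather than 68% exactly.

## How many modes? Selection rule

Each spectrum is fitted with one and with two DHO modes. The two-mode fit
always includes the one-mode optimum (second mode started at zero
intensity) among its starting points, so its minimised sum of squares can
never exceed the one-mode value. Two modes are accepted only if

1. the reduced $\chi^2$ improves by at least 15% (relative), and
2. neither mode has *collapsed*: intensity both insignificant
   (below $2\sigma_I$) and negligible (below 2% of the total inelastic
   intensity).

The 15% threshold cleanly separates the two regimes reported for the
measured spectra — a dramatic improvement (2.07 to 1.04) where the
transverse mode is real, versus a negligible change (1.50 to 1.48) where it
is not. The collapse test captures the observed behaviour that a superfluous
second DHO is driven towards zero intensity irrespective of its starting
point. It deliberately does **not** veto a sub-resolution mode whose
intensity is statistically degenerate with the elastic amplitude (large
$\sigma_I$ at large fitted $I$): that is a covariance degeneracy, not a
collapse, and the $\chi^2$ criterion is left to decide. The symmetric
"two-hump" residual diagnostic — two positive smoothed lobes at $\pm\omega$
outside the elastic half-width, mirror-matched within the smoothing window —
is recorded as supporting evidence but does not gate the decision.

In two-mode fits the lower-energy mode is labelled transverse and the
higher longitudinal; a lone mode is longitudinal.

## Dispersion and derived observables

Per-Q fits are assembled into two branches $\omega(Q), \Gamma(Q)$ with
presence flags (the transverse branch is only populated where the two-mode
model was selected). From these:

* **Sound speed**: weighted least-squares line through the origin over the
  low-Q window (defaults 8 nm$^{-1}$ longitudinal, 10 nm$^{-1}$ transverse;
  an acoustic branch has $\omega(0)=0$), converted with
  1519.2674 m s$^{-1}$ per meV nm.
* **Zone boundary $Q_\mathrm{min}$**: the longitudinal dispersion minimum,
  located by a weighted local quadratic through the lowest point and up to
  two neighbours per side inside a 10–20 nm$^{-1}$ window. The coarse Q
  resolution (~1.5 nm$^{-1}$) makes direct minimum picking too blunt; the
  local quadratic is exact for a true parabola and much more stable against
  single-point noise than a minimal 3-point vertex. Minima at the window
  edge are flagged, not returned silently.
* **Area per lipid**: $d = 2\pi/Q_\mathrm{min}$ (mean chain spacing) and
  $A_L = 2.64\,(9d/8)^2$ in Å$^2$, with the error propagated from
  $Q_\mathrm{min}$.
* **Damping ratio** $R = \omega/\Gamma$ per point, classified overdamped
  ($R<1$), critical ($|R-1|$ within its propagated error) or underdamped.
* **Phononic gap**: a contiguous run of absent transverse points at the
  low-Q end. The edge is reported as the midpoint between the last absent
  and first present Q, together with that bracketing interval — the Q
  spacing, not the midpoint, is the honest precision. The cluster size is
  $d_\mathrm{gap} = 2\pi/Q_\mathrm{gap}$. No gap is reported when the branch
  is present at the lowest measured Q.

## The forward simulator

`phase_scenario()` encodes the two study conditions with their published
values: gel (20 °C): $v_L = 2532$, $v_T = 582$ m/s,
$Q_\mathrm{min} = 15.4$ nm$^{-1}$, no gap; fluid (45 °C): $v_L = 2241$,
$v_T = 582$ m/s, $Q_\mathrm{min} = 14.2$ nm$^{-1}$, transverse branch
suppressed below 5 nm$^{-1}$. Both use 18 Q values spanning
2.47–27.29 nm$^{-1}$ (spacing 1.46 nm$^{-1}$, matching the instrument's Q
resolution), 97 energy points, and a 1.7 meV Pseudo-Voigt resolution. The
energy span ($\pm 15$ meV, symmetric) is a simulator convention: wide enough
to cover the ~10 meV longitudinal features with padding; the measured span
is not published.

Choices the data do not pin down, made once and documented here:

* **Dispersion shape.** $\omega(q) = S q$ (with $S = v/1519.2674$ meV nm)
  up to $q_c = 0.45\,Q_\mathrm{min}$, then a $C^1$ cubic Hermite segment
  descending to a minimum of depth $\omega_\mathrm{min}$ (2 meV
  longitudinal, 1 meV transverse) exactly at $Q_\mathrm{min}$, evenly
  reflected beyond it. This is the minimal shape with a genuinely linear
  low-Q regime (the measured branches are linear out to roughly 0.4–0.45 of
  $Q_\mathrm{min}$) and the published minimum position; a single sine arch
  has no linear regime at all and would make every low-Q slope estimate
  systematically low. It is a simulator convention, not a physical model.
* **Damping.** $\Gamma(q) = g_0 + g_1 q$ per branch: gel longitudinal
  (0.4, 0.12), gel transverse (1.0, 0.05), fluid longitudinal (0.8, 0.18),
  fluid transverse (0.8, 0.15) meV. These reproduce the reported damping
  phenomenology: gel modes underdamped at intermediate Q with the
  transverse damping ratio rising to a clear maximum there, fluid modes
  near critical damping, everything overdamped at high Q.
* **Intensities.** Longitudinal strength
  $I_L = 0.06\,N_\mathrm{peak}\,[1 + 2 e^{-(q-Q_\mathrm{min})^2/2(1.5)^2}]$:
  density modes couple through the static structure factor, which peaks at
  the chain-correlation peak, i.e. at the zone boundary. Transverse strength
  $I_T = 0.06\,N_\mathrm{peak}\,[1 + (2\,\mathrm{meV}/\omega)^2]$: an
  equipartition-flavoured boost (thermal amplitude $\propto kT/\omega^2$,
  saturated at a 2 meV scale) that makes the low-energy shear modes
  thermally intense — this is what renders the sub-resolution gel transverse
  mode detectable at the lowest Q, as it was in the measurement. Both put
  inelastic features at a few percent of the elastic intensity.
* **Statistics.** Elastic peak of $N_\mathrm{peak} = 5000$ expected counts,
  flat background of 20 counts — plausible for 90 s per point at a
  third-generation synchrotron — with Poisson noise per point and
  $\sigma = \sqrt{\max(\mathrm{counts},1)}$, the estimator a practitioner
  would use. Using observed rather than expected counts in $\sigma$ biases
  the mean reduced $\chi^2$ upward by a few percent at background-level
  counts; the calibration tests assert a [0.9, 1.1] band around 1.
* **Seeding.** One master seed; per-Q sub-seeds
  $(s + 104729\,i) \bmod (2^{31}-1)$, so datasets are reproducible and
  per-spectrum draws independent.

### What the simulator does *not* emulate

The elastic amplitude is constant in Q (no $S(Q,0)$ line shape, no
chain-correlation peak in the *elastic* channel), there are no optical or
localized modes, no mosaicity or geometry factors, no beam-damage drift, and
the dispersion closed form between the linear regime and the zone boundary
is invented. Passing tests therefore demonstrate that the *method* —
lineshape, selection, assembly, derived quantities — behaves correctly under
controlled, paper-consistent conditions; they do not validate the simulator
as a physical model of a bilayer, and results on real spectra will inherit
whatever the real $S(Q,\omega)$ does that the simulator omits (in
particular, mode-count selection near the zone boundary, where both
branches are overdamped and overlapping, remains intrinsically unstable at
realistic statistics — visible here as occasional transverse dropouts at
mid/high Q even in the gel scenario).

## Problem sizes used in the tests

The suite runs the statistical checks at the sizes a desk reproduction
supports: 100-replicate ensembles for recovery/coverage/χ² calibration,
20 seeds per scenario for mode-count selection, 20 end-to-end pipeline runs
of the fluid scenario for the gap/area/speed recovery property, and single
seeded end-to-end runs of both scenarios through the file-based pipeline.

## Known limitations

* Mode selection is binary (1 vs 2 modes); relaxational (ω = 0) models and
  mode counts above two are out of scope.
* Branch labelling by energy ordering can swap labels if a real system had
  crossing branches; the two measured conditions do not.
* The transverse sound speed from sparse low-Q transverse points is fragile
  in the fluid phase (the gap removes exactly the points the slope needs);
  it is reported with its error but should be read with care.
* Errors on derived quantities assume independent, Gaussian per-Q errors.
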