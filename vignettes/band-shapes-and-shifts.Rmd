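---
title: "Simulating absorption band shapes and the vertical-excitation redshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating absorption band shapes and the vertical-excitation redshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neaspec)
```

## The problem

Computed vertical excitation energies $E^v$ are routinely compared with
experimental absorption band maxima $E^{\max}$, yet the two are not the same
quantity: the band maximum sits systematically *below* the vertical
excitation, typically by $\delta = E^v - E^{\max} \approx 0-0.4$ eV. This
package provides the machinery to simulate band envelopes for harmonic model
systems, to understand where the redshift comes from, and to apply or fit
the shift in practical Gaussian-convolution spectra.

## The model

Each vibrational mode $r$ is an uncoupled harmonic coordinate shared by two
electronic states,

$$E_g = \tfrac{1}{2}\mu_r\omega_{g,r}^2 q_r^2,\qquad
  E_e = E^v + \tfrac{1}{2}\mu_r\eta_r\omega_{g,r}^2 (q_r-d_r)^2,$$

with $\eta_r = \omega_{e,r}^2/\omega_{g,r}^2$ the squared-frequency ratio
(softening for $\eta<1$) and $d_r$ the displacement of the excited minimum.
Internally everything is in Hartree atomic units ($\hbar = 1$); frequencies
are accepted in cm$^{-1}$, masses in amu, energies in eV, so no $\hbar$
bookkeeping leaks into the formulas. `vertical_excitation()` returns the gap
at the ground-state minimum, which exceeds the `E_v` parameter by the excited
reorganization term $\sum_r \tfrac12 \mu_r\eta_r\omega_{g,r}^2 d_r^2$ when
modes are displaced.

The band envelope is built with the nuclear-ensemble approach: geometries
are drawn from the ground-state harmonic Wigner distribution, whose position
marginal per mode is Gaussian with variance $\hbar/(2\mu\omega_g)$
(`sample_positions()`; momenta are never needed because the spectrum depends
on coordinates alone, and only the zero-temperature ground vibrational state
is sampled). Each geometry contributes a normalized Gaussian line
$g(x) = \exp(-x^2/w^2)/(w\sqrt{\pi})$ centred at its energy gap
(`mc_spectrum()`), under the Condon approximation of a constant transition
strength. The band maximum is the grid argmax refined by a parabola through
its two neighbours, with ties broken toward lower energy (`band_maximum()`).

```{r quick, eval = FALSE}
m <- model_degenerate_2mode(omega_g_cm1 = 1500, eta = 0.8)
measure_shift(m, n = 50000, seed = 1, w = 0.05)
```

## Why the maximum redshifts

For two degenerate softened modes with a shared minimum the band has a
closed form (`analytic_spectrum()`), controlled by
$A = \hbar(\omega_e^2-\omega_g^2)/\omega_g$. The intensity at photon energy
$E_P$ balances two factors: the ground-state population on the isoenergetic
hyperline $\Delta E_{ge}(q) = E_P$, largest at the equilibrium geometry, and
the length of that hyperline, which vanishes at the equilibrium geometry and
grows outward. The optimum sits at displaced geometries whose gap is below
$E^v$ — a purely semiclassical, multidimensional effect. Expanding the
derivative of the closed form to first order around $E^v$ gives the shift
law (`analytic_shift()`)

$$\delta = \frac{\hbar}{2}\frac{\omega_g^2-\omega_e^2}{\omega_g},$$

positive exactly when the excited state is softer. The first moment of the
band obeys a closely related thermal formula (`m1_shift()`), which at zero
temperature and two degenerate modes reduces to the first-order law exactly.
(The coth argument is implemented as $\hbar\omega_g/2k_BT$; a sometimes-seen
variant with $\omega_g^2$ inside the coth is dimensionally inconsistent and
does not reproduce that limit.)

Two numerical regimes deserve note, both verifiable with
`analytic_band_max()`:

* the first-order law is accurate for line widths $w \gtrsim |A|$ (about 10%
  at $w = 0.1$–$0.15$ eV for $\eta = 0.7$–$0.9$ at 1500 cm$^{-1}$), and
* as $w \to 0$ the exact peak of the two-mode band migrates back to $E^v$,
  because the gap density itself is maximal at its upper edge; the shift of
  a *narrow-line* band is carried by the interplay of many modes rather than
  by two.

In one dimension the band shows no systematic shift at all for small $w$
(`model_1v()`), which is the cleanest demonstration that the redshift is a
multidimensional phenomenon.

An important quantitative consequence of the zero-temperature ensemble: the
mean of the gap distribution lies below the vertical excitation by exactly
$\sum_r (\hbar\omega_{g,r}/4)(1-\eta_r)$ — the $T=0$ first-moment shift.
Since the per-mode gap densities are skewed toward low energies with a hard
upper fold, the smoothed band maximum always falls between that mean and the
upper edge. A single softened mode with $\eta = 0.8$ at 1500 cm$^{-1}$ can
therefore never push the band maximum more than about 0.01 eV below the
vertical excitation, no matter how the other (frequency-preserving) modes
are displaced; displacements of $\eta = 1$ modes only broaden the band
symmetrically. Large shifts require the frequency change to be spread over
many modes. The three-mode factory `model_3v()` makes these statements easy
to probe.

## Chosen defaults and their rationale

* **Line width** `w = 0.05` eV for ensemble spectra — the broadening used
  for molecular nuclear-ensemble simulations; sensitivity at
  `w` ∈ {0.01, 0.05, 0.1} eV is part of the test suite's checks.
* **Ensemble size** `n = 50000` for model systems (Monte-Carlo noise on the
  peak location well below 0.01 eV for sub-eV bands); the closed-form
  comparison uses `n = 2e5`.
* **Grid** 2001 points on $[E^v-2, E^v+1]$ eV (1.5 meV spacing), well below
  the 0.01 eV reporting precision; parabolic refinement removes the
  remaining grid bias.
* **Displacement units in `model_3v()`**: printed displacements of order
  10 au for modes of amu-scale mass are read as *mass-weighted* atomic
  units (bohr·√m$_e$), giving sub-eV band widths comparable to molecular
  absorption bands. The literal plain-bohr reading (available via
  `displacement = "bohr"`) makes a 10 au displacement at $\mu = 1$ amu
  correspond to a reorganization energy of over 100 eV and tens-of-eV-wide
  bands, which is not a useful regime; the container itself
  (`mode_spec()`) stays unit-faithful with `d` in bohr and an explicit
  reduced mass.
* **Monte-Carlo uncertainty** of a shift is assessed by replication over
  seeds (five by default in the reported summaries) rather than by an
  analytic error formula — the peak location has no simple closed-form
  variance.
* **RNG**: R's Mersenne-Twister, seeded per call; the seed and generator
  are recorded in the sample attributes, and equal seeds give bit-identical
  ensembles.

## Cross-section convolution and sub-band fitting

For practical spectra from vertical excitations and oscillator strengths,
`convolve_subbands()` evaluates (energies in eV, cross-section in
Å$^2$/molecule)

$$\sigma_A(E) = 0.619\, n \sum_i \frac{f_i}{\Gamma_i}
  \exp\!\left(-\frac{(E-E_i^v+\delta_i)^2}{\Gamma_i^2}\right),$$

where the 0.619 eV Å$^2$ prefactor is *computed* from fundamental constants
as $(\pi e^2\hbar/2m_ec\varepsilon_0)/\sqrt{\pi}$
(`cross_section_prefactor()`), $n$ is the refractive index (default 1, gas
phase), and $\Gamma_i$ is a $1/e$ half-width. The area under each sub-band
is $1.0975\,n f_i$ eV Å$^2$ — proportional to the oscillator strength. Peak
*height* goes as $f_i/\Gamma_i$; treating $f_i$ itself as the height has the
wrong functional form and is deliberately impossible through this interface.

`fit_subbands()` inverts the convolution: given a simulated spectrum and the
vertical excitations, it extracts $\delta_i$ and $\Gamma_i$ (optionally also
$f_i$) by bounded Levenberg–Marquardt with the analytic Jacobian.
Initialization at $\delta = 0.1$ eV and $\Gamma = 0.3$ eV reflects the
benchmark means below; bounds $\Gamma \in (0.01, 2)$ eV and
$\delta \in (-0.5, 1)$ eV keep the optimizer in the physically sensible
region. The number of sub-bands is the caller's choice (one per vertical
excitation with appreciable oscillator strength). Overlapping sub-bands can
trade intensity; a warning is raised when the Jacobian condition number
exceeds $10^6$. With near-degenerate verticals the fit is genuinely
non-identifiable and results should be read accordingly.

## The packaged benchmark

`load_benchmark()` ships 60 fitted sub-bands for 28 small organic molecules
(CC2 excited states, ADC(2) for four molecules with CC2 convergence
problems): vertical energy, oscillator strength, fitted shift and width per
sub-band. Summary statistics (`shift_statistics()`, computed over sub-bands,
population standard deviation by default) give mean $\delta \approx 0.11$ eV
with sd 0.08 eV, 80% of sub-bands at $\delta \ge 0.05$ eV, and widths
between 0.03 and 0.77 eV with mean 0.32 eV. That motivates the two rules of
thumb exposed by the package: estimate a band maximum as
`estimate_band_max(E_v)` $= E^v - 0.1$ eV, and use $\Gamma = 0.3$ eV when a
common width must be assumed. The transcription is guarded by embedded
checksums; molecule 12's width column duplicates its oscillator-strength
column in the source table (documented in `?load_benchmark`).

## What the synthetic models do and do not show

The harmonic two-state models emulate exactly one thing: how frequency
change, displacement and dimensionality shape a band envelope under
zero-temperature Wigner sampling. They contain no anharmonicity, no
Duschinsky rotation between mode sets, no temperature, no non-Condon
intensity variation, and no vibrational resolution — so passing tests on
these models validates the band-shape machinery and the shift laws, not the
accuracy of any electronic-structure method on real molecules. The packaged
benchmark plays the complementary role: it records what full ab initio
nuclear-ensemble simulations actually produced for real molecules, and the
package's statistics reproduce its printed summaries from the raw table.

## Numerical edge cases

* `analytic_spectrum()` is evaluated in log space through the normal CDF,
  so the product of a huge exponential and a vanishing erfc tail stays
  finite far above the band; mode stiffening ($A>0$) uses the exact mirror
  symmetry of the underlying integral.
* The 2-D quadrature oracle integrates one quadrant in polar coordinates
  restricted to the resonance annulus (panelled radially); outside it the
  integrand underflows to exact zeros that break adaptive error estimates.
* A flat spectrum has no unique maximum and errors; `eta = 0` (flat excited
  surface along a mode) is allowed, negative `eta` is not.
* Fits that stop without convergence still return their best parameters,
  flagged, with the residual norm.
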