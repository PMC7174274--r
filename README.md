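# neaspec

Photoabsorption band shapes for harmonic two-state models, and the redshift
between vertical excitation energies and band maxima.

Computed vertical excitations `E^v` are routinely compared with experimental
band maxima `E^max`, but the band maximum of a multidimensional molecule is
systematically redshifted below the vertical excitation by
`delta = E^v − E^max`, typically 0–0.4 eV. `neaspec` implements, for
spectroscopists and method developers:

* **Nuclear-ensemble band-shape simulation** on multimode harmonic
  ground/excited surfaces `E_g = ½μω_g²q²`,
  `E_e = E^v + ½μηω_g²(q−d)²` (with `η = ω_e²/ω_g²`): geometries sampled
  from the zero-temperature harmonic Wigner distribution (position variance
  `ħ/2μω_g` per mode), each contributing a normalized Gaussian line of
  width `w`, plus peak location with parabolic refinement
  (`sample_positions()`, `mc_spectrum()`, `measure_shift()`).
* **Closed-form two-mode band** and shift laws: the analytic band shape for
  two degenerate softened modes, the first-order shift law
  `delta = (ħ/2)(ω_g² − ω_e²)/ω_g`, the exact numerical peak, the thermal
  first-moment shift `Σ_r (ħ/4)((ω_g,r² − ω_e,r²)/ω_g,r) coth(ħω_g,r/2k_BT)`,
  and independent quadrature oracles (`analytic_spectrum()`,
  `analytic_shift()`, `analytic_band_max()`, `m1_shift()`,
  `brute_force_spectrum_2d()`).
* **Cross-section convolution and sub-band fitting**:
  `σ_A(E) = 0.619 n Σ_i (f_i/Γ_i) exp(−(E−E_i^v+δ_i)²/Γ_i²)` in
  Å²/molecule, with the 0.619 eV Å² prefactor derived from fundamental
  constants, and bounded least-squares extraction of per-sub-band shifts
  `δ_i` and widths `Γ_i` (`convolve_subbands()`, `fit_subbands()`,
  `cross_section_prefactor()`).
* **A packaged benchmark** of 60 fitted sub-bands across 28 small organic
  molecules with summary statistics and the practical band-maximum
  estimator `E^max ≈ E^v − 0.1 eV` (`load_benchmark()`,
  `shift_statistics()`, `estimate_band_max()`).

## Worked example

```r
library(neaspec)

# two degenerate 1500 cm-1 modes, 20% softer on excitation, E^v = 4.08 eV
m <- model_degenerate_2mode(omega_g_cm1 = 1500, eta = 0.8)
measure_shift(m, n = 50000, seed = 1, w = 0.05)
#> Band maximum: E_max = 4.0642 eV (parabolic refinement)
#>   shift delta = E_v - E_max = +0.0158 eV

analytic_shift(1500, eta = 0.8)   # first-order law: 0.0186 eV

st <- shift_statistics(load_benchmark(), "delta", threshold = 0.05)
c(mean = st$mean, sd = st$sd, frac = st$fraction_at_or_above)
#>   mean     sd   frac
#>  0.106  0.078  0.800

estimate_band_max(5.52)           # pyrimidine band 2: 5.42 eV
```

The simulated shift (+0.016 eV) sits a little below the first-order law
(0.0186 eV), as expected at `w = 0.05` eV; the benchmark statistics say that
across real molecules the fitted shifts average 0.11 eV with 80% of
sub-bands at or above 0.05 eV — hence the `E^v − 0.1 eV` rule of thumb for
estimating band maxima from vertical excitations alone.

A thin command-line wrapper is installed with the package
(`system.file("scripts", "neaspec", package = "neaspec")`) with subcommands
`simulate`, `analytic`, `shift`, `convolve`, `fit` and `benchmark-stats`.

See the vignette `vignettes/band-shapes-and-shifts.Rmd` for the model, the
origin of the redshift, default choices, and known limitations.

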