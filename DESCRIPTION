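Package: neaspec
Title: Nuclear-Ensemble Photoabsorption Band Shapes and Vertical-Excitation Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates UV/Vis photoabsorption band shapes for two-state
    multimode harmonic models with the semiclassical nuclear-ensemble
    approach (Wigner-distribution sampling of ground-state vibrations),
    and quantifies the redshift between the vertical excitation energy
    and the band maximum. Includes the closed-form band shape and
    first-order shift law for the degenerate two-mode model, the
    first-moment shift for general harmonic mode sets, Gaussian sub-band
    convolution of absorption cross-sections from vertical excitations
    and oscillator strengths with a prefactor derived from fundamental
    constants, least-squares extraction of per-sub-band shifts and
    widths, and a packaged 28-molecule / 60-sub-band benchmark of fitted
    shift values with summary statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
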