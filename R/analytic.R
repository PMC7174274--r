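#' Parameters of the closed-form two-mode band shape
#'
#' For two degenerate harmonic modes sharing the ground-state minimum, with
#' ground frequency `omega_g` and excited frequency `omega_e` (given either
#' directly or via `eta = omega_e^2/omega_g^2`), the nuclear-ensemble band
#' shape has a closed form governed by the curvature parameter
#' `A = hbar (omega_e^2 - omega_g^2) / omega_g` (eV). Mode softening
#' (`omega_e < omega_g`) gives `A < 0` and a band extending below the
#' vertical excitation.
#'
#' @param E_v_eV vertical excitation energy (eV).
#' @param omega_g_cm1 ground-state frequency (cm-1).
#' @param eta squared-frequency ratio; give this or `omega_e_cm1`.
#' @param omega_e_cm1 excited-state frequency (cm-1).
#' @param w Gaussian line width (eV), > 0.
#' @param k overall scale constant (dimensionless; k = 1 matches the
#'   normalized Monte-Carlo spectrum of [mc_spectrum()]).
#' @return object of class `analytic_band_params` with fields `E_v`,
#'   `omega_g`, `omega_e` (eV units for frequencies via `hbar omega`), `A`,
#'   `w`, `k`.
#' @export
analytic_band_params <- function(E_v_eV = 4.08, omega_g_cm1 = 1500,
                                 eta = NULL, omega_e_cm1 = NULL,
                                 w = 0.05, k = 1) {
  if (is.null(eta) == is.null(omega_e_cm1))
    stop("give exactly one of 'eta' or 'omega_e_cm1'")
  if (!is.null(eta)) {
    if (eta < 0) stop("eta must be >= 0")
    omega_e_cm1 <- omega_g_cm1 * sqrt(eta)
  }
  if (omega_g_cm1 <= 0) stop("omega_g must be positive")
  if (w <= 0) stop("line width 'w' must be positive")
  hw_g <- convert_unit(omega_g_cm1, "cm-1", "eV")  # hbar * omega_g, eV
  hw_e <- convert_unit(omega_e_cm1, "cm-1", "eV")
  A <- (hw_e^2 - hw_g^2) / hw_g                    # hbar(we^2-wg^2)/wg, eV
  structure(list(E_v = E_v_eV, hw_g = hw_g, hw_e = hw_e,
                 omega_g_cm1 = omega_g_cm1, omega_e_cm1 = omega_e_cm1,
                 A = A, w = w, k = k),
            class = "analytic_band_params")
}

#' Closed-form band shape of the degenerate two-mode model
#'
#' Evaluates
#' `sigma(E_p) = -(k/A) exp((w^2/A^2)(1 + (2A/w^2) dE)) *
#'   (1 + erf((w/A)(1 + (A/w^2) dE)))`,
#' with `dE = E_v - E_p`, the analytic integral of the two-mode
#' nuclear-ensemble band. Evaluation is done in log space (via the normal
#' CDF) so the product of a huge exponential and a vanishing erfc factor far
#' above the band stays finite. Parameters with `A > 0` (mode stiffening)
#' are handled by the exact reflection `sigma(A, dE) = sigma(-A, -dE)`.
#'
#' @param params an [analytic_band_params()] with `A != 0`.
#' @param E_p photon energies (eV), vectorized.
#' @return intensities (same arbitrary units as [mc_spectrum()] when
#'   `k = 1`).
#' @export
analytic_spectrum <- function(params, E_p) {
  stopifnot(inherits(params, "analytic_band_params"))
  A <- params$A; w <- params$w; k <- params$k
  if (A == 0)
    stop("A = 0 (omega_e == omega_g): the band is a single Gaussian of ",
         "width w at E_v; use that limit directly")
  dE <- params$E_v - E_p
  if (A > 0) { A <- -A; dE <- -dE }   # exact mirror symmetry of the integral
  z <- w / A + dE / w                 # erf argument
  logs <- log(-2 * k / A) + (w^2 / A^2 + 2 * dE / A) +
    stats::pnorm(sqrt(2) * z, log.p = TRUE)  # log(1 + erf(z)) - log 2
  exp(logs)
}

#' Quadrature oracle for the two-mode band shape
#'
#' Integrates the two-mode nuclear-ensemble band numerically, either as the
#' 1-D radial integral
#' `sigma = (k / (w sqrt(pi))) Int_0^Inf exp(-t - (dE + A t / 2)^2 / w^2) dt`
#' (`method = "radial"`, adaptive [stats::integrate()]), or as a genuine 2-D
#' quadrature of the dimensionless Gaussian-times-lineshape integrand over
#' the two mode coordinates (`method = "2d"`, [pracma::integral2()]). Serves
#' as the independent check of [analytic_spectrum()].
#'
#' @inheritParams analytic_spectrum
#' @param method quadrature scheme.
#' @param rel_tol requested relative tolerance (the 2-D scheme supports down
#'   to 1e-8).
#' @return intensities at `E_p`.
#' @export
brute_force_spectrum_2d <- function(params, E_p,
                                    method = c("radial", "2d"),
                                    rel_tol = 1e-8) {
  # (radial integrate() accepts tighter tolerances than integral2)
  stopifnot(inherits(params, "analytic_band_params"))
  method <- match.arg(method)
  A <- params$A; w <- params$w; k <- params$k
  one <- function(dE) {
    if (method == "radial") {
      res <- stats::integrate(function(t) exp(-t - (dE + A * t / 2)^2 / w^2),
                              0, Inf, rel.tol = rel_tol, abs.tol = 0,
                              stop.on.error = FALSE)
      if (res$message != "OK")
        stop("quadrature did not converge: ", res$message,
             " (dE = ", signif(dE, 6), ")")
      k / (w * sqrt(pi)) * res$value
    } else {
      # q_r in units of 1/sqrt(alpha): rho du dv = exp(-(u^2+v^2))/pi du dv.
      # The integrand lives on a resonance annulus; quadrature panels where
      # it underflows to exactly zero break the adaptive error estimate, so
      # integrate one quadrant in polar form restricted to the support.
      Lmax2 <- max(200, 4 * abs(dE / A) + 50)  # covers the resonance radius
      lf <- function(r2) -r2 - (dE + A * r2 / 2)^2 / w^2
      opt <- stats::optimize(lf, c(0, Lmax2), maximum = TRUE)
      r2pk <- opt$maximum; m0 <- opt$objective
      drop_ <- 80  # exp(-80) dynamic range retained around the maximum
      r2lo <- if (lf(0) > m0 - drop_) 0 else
        stats::uniroot(function(x) lf(x) - (m0 - drop_), c(0, r2pk),
                       tol = 1e-14)$root
      hi0 <- r2pk + 1
      while (lf(hi0) > m0 - drop_) hi0 <- hi0 * 2
      r2hi <- stats::uniroot(function(x) lf(x) - (m0 - drop_),
                             c(r2pk, hi0), tol = 1e-14)$root
      f <- function(u, v) exp(lf(u^2 + v^2) - m0)
      # panel the radial range so the startup rule of each sub-quadrature
      # resolves the annulus instead of accepting an optimistic estimate
      brk <- sqrt(seq(r2lo, r2hi, length.out = 9))
      val <- 0
      for (j in seq_len(length(brk) - 1L)) {
        qj <- tryCatch(
          pracma::integral2(f, 0, pi / 2, brk[j], brk[j + 1L],
                            sector = TRUE, reltol = max(rel_tol, 1e-9))$Q,
          error = function(e)
            stop("2-D quadrature did not converge (dE = ", signif(dE, 6),
                 ", radial panel ", j, "): ", conditionMessage(e),
                 call. = FALSE))
        val <- val + qj
      }
      k / (w * pi^1.5) * exp(m0) * 4 * val
    }
  }
  vapply(params$E_v - E_p, one, numeric(1))
}

#' First-order band-maximum shift law for two degenerate modes
#'
#' `delta = E_v - E_max = (hbar/2) (omega_g^2 - omega_e^2) / omega_g`,
#' obtained by expanding the derivative of the closed-form band to first
#' order in the photon energy around the vertical excitation. Positive
#' exactly when the excited state is softer (`omega_e < omega_g`), i.e. the
#' band maximum is redshifted. The first-order law is accurate when the line
#' width is not small compared with `|A|`; the exact peak of the closed form
#' is available from [analytic_band_max()].
#'
#' @param omega_g_cm1 ground frequency (cm-1), > 0.
#' @param eta squared-frequency ratio; give this or `omega_e_cm1`.
#' @param omega_e_cm1 excited frequency (cm-1).
#' @return shift in eV.
#' @export
analytic_shift <- function(omega_g_cm1, eta = NULL, omega_e_cm1 = NULL) {
  if (is.null(eta) == is.null(omega_e_cm1))
    stop("give exactly one of 'eta' or 'omega_e_cm1'")
  if (any(omega_g_cm1 <= 0)) stop("omega_g must be positive")
  if (!is.null(eta)) omega_e_cm1 <- omega_g_cm1 * sqrt(eta)
  hw_g <- convert_unit(omega_g_cm1, "cm-1", "eV")
  hw_e <- convert_unit(omega_e_cm1, "cm-1", "eV")
  0.5 * (hw_g^2 - hw_e^2) / hw_g
}

#' Exact band maximum of the closed-form two-mode band
#'
#' Numerical argmax of [analytic_spectrum()], so the error of the
#' first-order law [analytic_shift()] can be inspected.
#'
#' @param params an [analytic_band_params()].
#' @return list with `E_max` and `shift_delta` (eV).
#' @export
analytic_band_max <- function(params) {
  stopifnot(inherits(params, "analytic_band_params"))
  span <- 10 * (abs(params$A) + params$w)
  opt <- stats::optimize(function(E) analytic_spectrum(params, E),
                         lower = params$E_v - span,
                         upper = params$E_v + span,
                         maximum = TRUE, tol = 1e-10)
  list(E_max = opt$maximum, shift_delta = params$E_v - opt$maximum)
}

#' Vertical-excitation-to-first-moment shift of a harmonic mode set
#'
#' For harmonic ground and excited surfaces (vertical-Hessian construction)
#' the band's first moment (centre of gravity) M1 lies below the vertical
#' excitation by
#' `E_v - M1 = sum_r (hbar/4) ((omega_g,r^2 - omega_e,r^2)/omega_g,r) *
#'   coth(hbar omega_g,r / (2 kB T))`.
#' At `T = 0` the coth factor is its limit 1; for two degenerate modes the
#' zero-temperature value equals [analytic_shift()] exactly. (A commonly
#' printed variant squares the frequency inside the coth; that form is
#' dimensionally inconsistent and the standard thermal-occupation argument
#' `hbar omega / 2 kB T` is used here.)
#'
#' @param omega_g_cm1,omega_e_cm1 per-mode frequencies (cm-1), equal length.
#' @param temperature temperature in kelvin, >= 0.
#' @return shift `E_v - M1` in eV.
#' @export
m1_shift <- function(omega_g_cm1, omega_e_cm1, temperature = 0) {
  if (length(omega_g_cm1) != length(omega_e_cm1))
    stop("frequency vectors must have equal length")
  if (any(omega_g_cm1 <= 0) || any(omega_e_cm1 <= 0))
    stop("frequencies must be positive")
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      temperature < 0)
    stop("temperature must be a single value >= 0 kelvin")
  hw_g <- convert_unit(omega_g_cm1, "cm-1", "eV")
  hw_e <- convert_unit(omega_e_cm1, "cm-1", "eV")
  cothf <- if (temperature == 0) rep(1, length(hw_g)) else {
    x <- hw_g / (2 * .codata$kB_eV * temperature)
    1 / tanh(x)
  }
  sum(0.25 * (hw_g^2 - hw_e^2) / hw_g * cothf)
}
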