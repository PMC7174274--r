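#' Gaussian sub-bands of an absorption cross-section
#'
#' A sub-band is one vertical excitation's contribution to the absorption
#' cross-section: vertical energy `E_v` (eV), oscillator strength `f`
#' (dimensionless), redshift `delta` (eV) of the sub-band peak below `E_v`,
#' and width `Gamma` (eV). `Gamma` is the 1/e half-width of the Gaussian
#' (not a FWHM and not a standard deviation).
#'
#' @param E_v,f,delta,Gamma equal-length numeric vectors (recycled scalars
#'   allowed); `Gamma > 0`, `f >= 0`.
#' @return a `data.frame` of class `subbands` with those four columns.
#' @export
subbands <- function(E_v, f, delta = 0, Gamma = 0.3) {
  d <- if (length(E_v) == 0L)
    data.frame(E_v = numeric(0), f = numeric(0), delta = numeric(0),
               Gamma = numeric(0))
  else data.frame(E_v = E_v, f = f, delta = delta, Gamma = Gamma)
  if (any(d$Gamma <= 0)) stop("all Gamma must be positive")
  if (any(d$f < 0)) stop("oscillator strengths must be nonnegative")
  class(d) <- c("subbands", "data.frame")
  d
}

#' Cross-section convolution prefactor from fundamental constants
#'
#' The Gaussian convolution of vertical excitations into an absorption
#' cross-section (energies in eV, cross-section in Angstrom^2/molecule) is
#' `sigma_A(E) = C n sum_i (f_i / Gamma_i) exp(-(E - E_v,i + delta_i)^2 /
#' Gamma_i^2)` with `C = (pi e^2 hbar / (2 m_e c eps0)) / sqrt(pi)`.
#' Both constants are computed from CODATA 2018 values, never hard-coded:
#' the integral constant `pi e^2 hbar / (2 m_e c eps0)` is ~1.0975 eV A^2
#' and the peak prefactor `C` is ~0.619 eV A^2.
#'
#' @param integral if `TRUE` return the un-divided integral constant
#'   `pi e^2 hbar / (2 m_e c eps0)` instead of the peak prefactor.
#' @return scalar, eV Angstrom^2.
#' @export
cross_section_prefactor <- function(integral = FALSE) {
  cc <- .codata
  # pi e^2 hbar / (2 m_e c eps0) in SI (J m^2), then to eV A^2
  val_SI <- pi * cc$e_C^2 * cc$hbar_Js / (2 * cc$me_kg * cc$c_ms * cc$eps0_SI)
  val <- val_SI / cc$e_C / 1e-20
  if (integral) val else val / sqrt(pi)
}

#' Convolve vertical excitations into an absorption cross-section
#'
#' Evaluates the sub-band Gaussian convolution (see
#' [cross_section_prefactor()]) on an energy grid. Each sub-band peaks at
#' `E_v - delta` with height `C n f / Gamma`; its area is
#' `sqrt(pi) C n f`, proportional to the oscillator strength. An empty
#' sub-band table gives a zero spectrum.
#'
#' @param bands a [subbands()] table (or data.frame with columns `E_v`, `f`,
#'   `delta`, `Gamma`).
#' @param n_refr refractive index (default 1, gas phase).
#' @param grid strictly increasing photon-energy grid (eV).
#' @return a [nea_spectrum()] with intensities in Angstrom^2/molecule.
#' @export
convolve_subbands <- function(bands, grid, n_refr = 1) {
  if (nrow(bands) > 0 && any(bands$Gamma <= 0))
    stop("all Gamma must be positive")
  pref <- cross_section_prefactor()
  sig <- numeric(length(grid))
  for (i in seq_len(nrow(bands))) {
    z <- (grid - bands$E_v[i] + bands$delta[i]) / bands$Gamma[i]
    sig <- sig + bands$f[i] / bands$Gamma[i] * exp(-z * z)
  }
  nea_spectrum(grid, pref * n_refr * sig,
               metadata = list(units = "A^2/molecule", n_refr = n_refr,
                               n_bands = nrow(bands)))
}

# model cross-section and its analytic Jacobian w.r.t. the free parameters
.conv_model <- function(E, E_v, f, delta, Gamma, n_refr, pref) {
  ns <- length(E_v)
  z <- outer(E, E_v - delta, "-") / rep(Gamma, each = length(E))
  g <- exp(-z * z)
  amp <- pref * n_refr * f / Gamma
  list(value = drop(g %*% amp), z = z, g = g, amp = amp)
}

#' Fit Gaussian sub-bands to a simulated spectrum
#'
#' Least-squares extraction of the per-sub-band shifts `delta_i` and widths
#' `Gamma_i` from a spectrum, with the vertical energies `E_v,i` held fixed
#' and the oscillator strengths `f_i` fixed by default (set `optimize_f` to
#' also relax them). The model is the cross-section convolution of
#' [convolve_subbands()]; fitting uses bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm]) with the analytic Jacobian. Defaults start each
#' sub-band at `delta = 0.1` eV and `Gamma = 0.3` eV; bounds are
#' `Gamma in (0.01, 2)` eV and `delta in (-0.5, 1)` eV.
#'
#' @param spectrum a [nea_spectrum()] covering the verticals' energy region,
#'   in Angstrom^2/molecule.
#' @param verticals data.frame with columns `E_v` and `f` (one row per
#'   sub-band), or a [subbands()] table whose `delta`/`Gamma` columns are
#'   ignored.
#' @param optimize_f also optimize the oscillator strengths.
#' @param n_refr refractive index.
#' @param delta_init,Gamma_init starting values (recycled).
#' @return object of class `subband_fit`: list with `bands` (a [subbands()]
#'   table of fitted parameters), `residual_norm`, `fixed` (which parameter
#'   families were held fixed), `converged`, `info`, `message`, and
#'   `jacobian_condition`.
#' @export
fit_subbands <- function(spectrum, verticals, optimize_f = FALSE,
                         n_refr = 1, delta_init = 0.1, Gamma_init = 0.3) {
  stopifnot(inherits(spectrum, "nea_spectrum"))
  if (nrow(verticals) < 1L) stop("need at least one sub-band")
  E <- spectrum$energies; y <- spectrum$intensities
  E_v <- verticals$E_v; f0 <- verticals$f
  ns <- length(E_v)
  if (min(E_v) < min(E) || max(E_v) > max(E))
    stop("spectrum grid does not cover the vertical excitations")
  npar <- 2L * ns + if (optimize_f) ns else 0L
  if (length(E) < npar)
    stop("fewer grid points (", length(E), ") than free parameters (",
         npar, ")")
  pref <- cross_section_prefactor()

  delta0 <- rep_len(delta_init, ns); Gamma0 <- rep_len(Gamma_init, ns)
  par0 <- c(delta0, Gamma0, if (optimize_f) f0)
  lower <- c(rep(-0.5, ns), rep(0.01, ns), if (optimize_f) rep(0, ns))
  upper <- c(rep(1.0, ns), rep(2.0, ns), if (optimize_f) rep(Inf, ns))

  unpack <- function(p) list(delta = p[1:ns], Gamma = p[ns + 1:ns],
                             f = if (optimize_f) p[2 * ns + 1:ns] else f0)
  resid_fn <- function(p) {
    q <- unpack(p)
    .conv_model(E, E_v, q$f, q$delta, q$Gamma, n_refr, pref)$value - y
  }
  jac_fn <- function(p) {
    q <- unpack(p)
    m <- .conv_model(E, E_v, q$f, q$delta, q$Gamma, n_refr, pref)
    # d sigma / d delta_i = amp_i * g_i * (-2 z_i / Gamma_i)
    Jd <- m$g * sweep(m$z, 2L, -2 * m$amp / q$Gamma, "*")
    # d sigma / d Gamma_i = amp_i * g_i * (2 z_i^2 - 1) / Gamma_i
    Jg <- m$g * (2 * m$z^2 - 1) * rep(m$amp / q$Gamma, each = length(E))
    J <- cbind(Jd, Jg)
    if (optimize_f) J <- cbind(J, sweep(m$g, 2L, pref * n_refr / q$Gamma, "*"))
    J
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = 500, ftol = 1e-14, ptol = 1e-12, gtol = 0))
  q <- unpack(fit$par)
  converged <- fit$info %in% 1:4
  J <- jac_fn(fit$par)
  cond <- kappa(J, exact = TRUE)
  if (!converged)
    warning("sub-band fit did not converge (info = ", fit$info, "): ",
            fit$message, "; returning best parameters so far")
  if (is.finite(cond) && cond > 1e6)
    warning(sprintf(
      "ill-conditioned fit (Jacobian condition number %.3g): overlapping sub-bands may trade intensity",
      cond))
  structure(list(
    bands = subbands(E_v, q$f, q$delta, q$Gamma),
    residual_norm = sqrt(sum(resid_fn(fit$par)^2)),
    fixed = c(E_v = TRUE, f = !optimize_f),
    converged = converged, info = fit$info, message = fit$message,
    jacobian_condition = cond), class = "subband_fit")
}

#' @export
print.subband_fit <- function(x, ...) {
  cat(sprintf("Sub-band fit (%d bands, residual norm %.3g, %s)\n",
              nrow(x$bands), x$residual_norm,
              if (x$converged) "converged" else "NOT converged"))
  print.data.frame(x$bands, digits = 4)
  invisible(x)
}

#' Estimate a band maximum from a vertical excitation
#'
#' `E_max = E_v - delta_bar`, using the benchmark mean shift
#' `delta_bar = 0.1` eV by default; see [load_benchmark()].
#'
#' @param E_v vertical excitation energies (eV).
#' @param delta_bar mean shift to subtract (eV).
#' @return estimated band maxima (eV).
#' @export
estimate_band_max <- function(E_v, delta_bar = 0.1) {
  stopifnot(is.finite(delta_bar))
  E_v - delta_bar
}
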