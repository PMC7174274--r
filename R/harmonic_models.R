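#' Specify one vibrational mode of a two-state harmonic model
#'
#' A mode is an uncoupled harmonic coordinate shared by the ground and
#' excited electronic states. The ground-state surface along coordinate `q`
#' (bohr) is `(1/2) mu omega_g^2 q^2`; the excited-state surface is
#' `(1/2) mu eta omega_g^2 (q - d)^2` on top of the vertical energy, where
#' `eta = omega_e^2 / omega_g^2` is the squared-frequency ratio describing
#' mode softening (`eta < 1`) or stiffening (`eta > 1`) upon excitation.
#'
#' @param omega_g ground-state frequency, in `omega_unit` (default cm-1).
#' @param eta squared-frequency ratio `omega_e^2/omega_g^2`; must be >= 0
#'   (`eta = 0`, a flat excited surface along the mode, is allowed).
#' @param d displacement of the excited-state minimum along the coordinate,
#'   in bohr.
#' @param mu reduced mass, in `mass_unit` (default amu).
#' @param omega_unit,mass_unit input units for `omega_g` and `mu`.
#' @return an object of class `mode_spec` with fields `omega_g` (hartree,
#'   i.e. the angular frequency in atomic units), `eta`, `d` (bohr) and
#'   `mu` (electron masses).
#' @export
mode_spec <- function(omega_g, eta = 1, d = 0, mu = 1,
                      omega_unit = "cm-1", mass_unit = "amu") {
  omega <- convert_unit(omega_g, omega_unit, "hartree")
  mu_me <- convert_unit(mu, mass_unit, "m_e")
  stopifnot(length(omega) == 1L, length(eta) == 1L,
            length(d) == 1L, length(mu_me) == 1L)
  if (!is.finite(omega) || omega <= 0) stop("omega_g must be positive")
  if (!is.finite(mu_me) || mu_me <= 0) stop("mu must be positive")
  if (!is.finite(eta) || eta < 0)
    stop("eta must be >= 0 (the excited squared frequency cannot be negative)")
  if (!is.finite(d)) stop("d must be finite")
  structure(list(omega_g = omega, eta = eta, d = d, mu = mu_me),
            class = "mode_spec")
}

#' Two-state multimode harmonic model
#'
#' Bundles a vertical energy parameter with a list of [mode_spec()] modes.
#' `E_v` is the energy offset of the excited surface at its minimum relative
#' to the ground-state minimum energy (zero); when all displacements vanish
#' it equals the vertical excitation energy exactly. With displaced modes the
#' actual vertical excitation (the energy gap at the ground-state minimum) is
#' `E_v + sum_r (1/2) mu_r eta_r omega_{g,r}^2 d_r^2`; see
#' [vertical_excitation()].
#'
#' @param E_v vertical energy parameter, in `energy_unit` (default eV).
#' @param modes a single [mode_spec()] or a list of them (>= 1 mode).
#' @param energy_unit input unit of `E_v`.
#' @param label optional description carried into spectra metadata.
#' @return object of class `two_state_model` with `E_v` in hartree.
#' @export
two_state_model <- function(E_v, modes, energy_unit = "eV", label = NULL) {
  if (inherits(modes, "mode_spec")) modes <- list(modes)
  if (!is.list(modes) || length(modes) < 1L ||
      !all(vapply(modes, inherits, logical(1), "mode_spec")))
    stop("'modes' must be a non-empty list of mode_spec objects")
  structure(list(E_v = convert_unit(E_v, energy_unit, "hartree"),
                 modes = modes,
                 label = label %||% sprintf("%d-mode two-state model",
                                            length(modes))),
            class = "two_state_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

n_modes <- function(model) length(model$modes)

mode_field <- function(model, field)
  vapply(model$modes, `[[`, numeric(1), field)

# coerce q to an n x n_modes matrix, checking dimensions
.q_matrix <- function(model, q) {
  k <- n_modes(model)
  if (is.null(dim(q))) {
    if (length(q) != k)
      stop("coordinate vector has length ", length(q),
           " but the model has ", k, " modes")
    q <- matrix(q, nrow = 1L)
  } else {
    q <- as.matrix(q)
    if (ncol(q) != k)
      stop("coordinate matrix has ", ncol(q),
           " columns but the model has ", k, " modes")
  }
  q
}

.drop1 <- function(x) if (length(x) == 1L) x[[1L]] else x

#' Ground-state potential energy
#'
#' `sum_r (1/2) mu_r omega_{g,r}^2 q_r^2`, zero at the ground minimum.
#'
#' @param model a [two_state_model()].
#' @param q coordinates in bohr: a vector of length `n_modes`, or an
#'   `n x n_modes` matrix of geometries.
#' @return energy in hartree (one value per geometry).
#' @export
ground_energy <- function(model, q) {
  q <- .q_matrix(model, q)
  k2 <- 0.5 * mode_field(model, "mu") * mode_field(model, "omega_g")^2
  .drop1(drop(q^2 %*% k2))
}

#' Excited-state potential energy
#'
#' `E_v + sum_r (1/2) mu_r eta_r omega_{g,r}^2 (q_r - d_r)^2`.
#'
#' @inheritParams ground_energy
#' @return energy in hartree (one value per geometry).
#' @export
excited_energy <- function(model, q) {
  q <- .q_matrix(model, q)
  k2 <- 0.5 * mode_field(model, "mu") * mode_field(model, "eta") *
    mode_field(model, "omega_g")^2
  dq <- sweep(q, 2L, mode_field(model, "d"))
  .drop1(drop(model$E_v + dq^2 %*% k2))
}

#' Ground-to-excited energy gap
#'
#' `excited_energy(model, q) - ground_energy(model, q)`. The photon energy at
#' which a geometry `q` contributes to the semiclassical spectrum (resonance
#' condition).
#'
#' @inheritParams ground_energy
#' @return gap in hartree (one value per geometry).
#' @export
energy_gap <- function(model, q) {
  excited_energy(model, q) - ground_energy(model, q)
}

#' Vertical excitation energy of a model
#'
#' The energy gap at the ground-state minimum (all coordinates zero). Equals
#' the `E_v` parameter when all displacements are zero.
#'
#' @param model a [two_state_model()].
#' @param unit output energy unit.
#' @return scalar energy.
#' @export
vertical_excitation <- function(model, unit = "eV") {
  convert_unit(energy_gap(model, rep(0, n_modes(model))), "hartree", unit)
}

#' @export
print.two_state_model <- function(x, ...) {
  cat("Two-state harmonic model:", x$label, "\n")
  cat(sprintf("  E_v parameter: %.4f eV; vertical excitation: %.4f eV\n",
              .ha2ev(x$E_v), vertical_excitation(x)))
  for (i in seq_along(x$modes)) {
    m <- x$modes[[i]]
    cat(sprintf(
      "  mode %d: omega_g = %.1f cm-1, eta = %.3g, d = %.4g bohr, mu = %.3g amu\n",
      i, convert_unit(m$omega_g, "hartree", "cm-1"), m$eta, m$d,
      convert_unit(m$mu, "m_e", "amu")))
  }
  invisible(x)
}

# ---- built-in factories ---------------------------------------------------

#' Single-mode (1V) benchmark model
#'
#' One vibrational mode with `E_v` = 4.08 eV, `omega_g` = 1500 cm-1 and
#' `mu` = 1 amu. In one dimension the band maximum shows no systematic shift
#' from the vertical excitation as the line width becomes small.
#'
#' @param eta squared-frequency ratio of the mode.
#' @param d displacement of the excited minimum (bohr).
#' @param E_v_eV,omega_g_cm1,mu_amu model parameters.
#' @return a [two_state_model()].
#' @export
model_1v <- function(eta = 1, d = 0, E_v_eV = 4.08, omega_g_cm1 = 1500,
                     mu_amu = 1) {
  two_state_model(E_v_eV,
                  mode_spec(omega_g_cm1, eta = eta, d = d, mu = mu_amu),
                  label = "1V single-mode model")
}

#' Three-mode (3V) benchmark model
#'
#' Three uncoupled modes with ground frequencies 1800, 1500 and 1000 cm-1,
#' `E_v` = 4.08 eV and `mu` = 1 amu for every mode. The middle mode carries
#' the frequency change `eta2` and a fixed displacement `d2`; the outer modes
#' keep their frequencies (`eta = 1`) and share the displacement `d13`.
#'
#' Displacements are accepted either in mass-weighted atomic units
#' (`bohr * sqrt(m_e)`, the default, converted internally to bohr via
#' `d / sqrt(mu)`) or literally in bohr. The mass-weighted reading yields
#' sub-eV band widths comparable to molecular absorption bands; the literal
#' bohr reading with `mu` = 1 amu produces tens-of-eV-wide bands and is kept
#' only for completeness.
#'
#' @param eta2 squared-frequency ratio of the 1500 cm-1 mode.
#' @param d13 displacement shared by the 1800 and 1000 cm-1 modes.
#' @param d2 displacement of the 1500 cm-1 mode (default 10).
#' @param displacement units of `d13`/`d2`: `"mass-weighted"` (au) or
#'   `"bohr"`.
#' @param E_v_eV,mu_amu remaining model parameters.
#' @return a [two_state_model()].
#' @export
model_3v <- function(eta2 = 0.8, d13 = 0, d2 = 10,
                     displacement = c("mass-weighted", "bohr"),
                     E_v_eV = 4.08, mu_amu = 1) {
  displacement <- match.arg(displacement)
  mu_me <- convert_unit(mu_amu, "amu", "m_e")
  conv <- if (displacement == "mass-weighted") 1 / sqrt(mu_me) else 1
  omegas <- c(1800, 1500, 1000)
  etas <- c(1, eta2, 1)
  ds <- c(d13, d2, d13) * conv
  modes <- lapply(1:3, function(r)
    mode_spec(omegas[r], eta = etas[r], d = ds[r], mu = mu_amu))
  two_state_model(E_v_eV, modes,
                  label = sprintf("3V model (eta2 = %.2g, d13 = %.3g %s)",
                                  eta2, d13, displacement))
}

#' Degenerate two-mode model with a shared minimum
#'
#' Two identical modes (`omega_g`, `eta`) with no displacement. This is the
#' model for which the band shape has a closed form ([analytic_spectrum()])
#' and the band-maximum shift obeys the first-order law [analytic_shift()].
#'
#' @param omega_g_cm1 ground frequency of both modes (cm-1).
#' @param eta squared-frequency ratio of both modes.
#' @param E_v_eV,mu_amu remaining model parameters.
#' @return a [two_state_model()].
#' @export
model_degenerate_2mode <- function(omega_g_cm1 = 1500, eta = 0.8,
                                   E_v_eV = 4.08, mu_amu = 1) {
  m <- mode_spec(omega_g_cm1, eta = eta, d = 0, mu = mu_amu)
  two_state_model(E_v_eV, list(m, m),
                  label = sprintf("degenerate 2-mode model (eta = %.2g)", eta))
}

# ---- model files ----------------------------------------------------------

#' Read or write a model specification file
#'
#' Models are stored as YAML (`.yml`/`.yaml`) or JSON (`.json`) with keys
#' `E_v_eV` and `modes`, a list of records with fields `omega_g_cm1`, `eta`,
#' `d_bohr` and `mu_amu` (missing fields default to `eta = 1`, `d_bohr = 0`,
#' `mu_amu = 1`).
#'
#' @param path file path; format chosen by extension.
#' @param model a [two_state_model()] (for `write_model`).
#' @return `read_model` returns a [two_state_model()]; `write_model` returns
#'   `path` invisibly.
#' @export
read_model <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (is.null(spec$E_v_eV) || is.null(spec$modes))
    stop("model file must contain 'E_v_eV' and 'modes'")
  modes <- lapply(spec$modes, function(m)
    mode_spec(m$omega_g_cm1,
              eta = m$eta %||% 1,
              d = m$d_bohr %||% 0,
              mu = m$mu_amu %||% 1))
  two_state_model(spec$E_v_eV, modes, label = spec$label %||% basename(path))
}

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  spec <- list(
    E_v_eV = .ha2ev(model$E_v),
    label = model$label,
    modes = lapply(model$modes, function(m)
      list(omega_g_cm1 = convert_unit(m$omega_g, "hartree", "cm-1"),
           eta = m$eta, d_bohr = m$d,
           mu_amu = convert_unit(m$mu, "m_e", "amu"))))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(spec, path, precision = 15)
  invisible(path)
}
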