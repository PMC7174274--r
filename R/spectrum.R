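#' Spectrum container
#'
#' A band shape on a strictly increasing photon-energy grid. Intensities are
#' in arbitrary units for model-system spectra (overall scale constant k = 1)
#' and in Angstrom^2 / molecule when produced by [convolve_subbands()].
#'
#' @param energies strictly increasing photon energies (eV).
#' @param intensities nonnegative intensities, same length.
#' @param w Gaussian line width used to build the spectrum (eV), if any.
#' @param metadata named list (model label, n, seed, E_v, units, ...).
#' @return object of class `nea_spectrum`.
#' @export
nea_spectrum <- function(energies, intensities, w = NA_real_,
                         metadata = list()) {
  energies <- as.numeric(energies); intensities <- as.numeric(intensities)
  if (length(energies) != length(intensities))
    stop("energies and intensities must have the same length")
  if (any(diff(energies) <= 0))
    stop("energies must be strictly increasing")
  if (any(intensities < 0))
    stop("intensities must be nonnegative")
  structure(list(energies = energies, intensities = intensities,
                 w = w, metadata = metadata),
            class = "nea_spectrum")
}

#' @export
print.nea_spectrum <- function(x, ...) {
  cat(sprintf("Spectrum: %d points on [%.3f, %.3f] eV\n",
              length(x$energies), min(x$energies), max(x$energies)))
  if (is.finite(x$w)) cat(sprintf("  line width w = %g eV\n", x$w))
  if (!is.null(x$metadata$model)) cat("  model:", x$metadata$model, "\n")
  invisible(x)
}

#' @export
plot.nea_spectrum <- function(x, ...) {
  plot(x$energies, x$intensities, type = "l",
       xlab = "photon energy (eV)", ylab = "intensity", ...)
  invisible(x)
}

#' Write / read a spectrum as two-column CSV
#'
#' Columns `energy_eV,intensity` with a header line and plain decimal
#' notation.
#'
#' @param spectrum a [nea_spectrum()].
#' @param path file path.
#' @return `write_spectrum_csv` returns `path` invisibly; `read_spectrum_csv`
#'   returns a [nea_spectrum()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(energy_eV = spectrum$energies,
                              intensity = spectrum$intensities),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("energy_eV", "intensity") %in% names(d)))
    stop("spectrum CSV must have columns 'energy_eV' and 'intensity'")
  nea_spectrum(d$energy_eV, d$intensity, metadata = list(source = path))
}

#' Monte-Carlo band shape from an ensemble of energy gaps
#'
#' Builds the semiclassical nuclear-ensemble spectrum as a weighted sum of
#' normalized Gaussian line shapes `g(x) = exp(-x^2/w^2) / (w sqrt(pi))`
#' centred at each sampled gap:
#' `I(E) = (sum_j w_j)^-1 sum_j w_j g(gap_j - E)`.
#' Uniform weights correspond to the Condon approximation with a constant
#' oscillator strength. With the overall constant k = 1 the spectrum
#' integrates to one over an unbounded grid.
#'
#' @param gaps sampled vertical gaps (eV), nonempty.
#' @param weights nonnegative weights, one per gap; `NULL` for uniform.
#' @param grid strictly increasing evaluation grid (eV).
#' @param w line width (eV), > 0. This is the 1/e half-width of `g`.
#' @param metadata passed to [nea_spectrum()].
#' @return a [nea_spectrum()].
#' @export
mc_spectrum <- function(gaps, weights = NULL, grid, w, metadata = list()) {
  if (length(gaps) == 0L) stop("'gaps' must be nonempty")
  if (!is.numeric(w) || length(w) != 1L || w <= 0)
    stop("line width 'w' must be positive")
  if (is.null(weights)) weights <- rep(1, length(gaps))
  if (length(weights) != length(gaps))
    stop("'weights' must match 'gaps' in length")
  if (any(weights < 0)) stop("'weights' must be nonnegative")
  wt <- weights / sum(weights)
  norm <- 1 / (w * sqrt(pi))
  # chunk the grid so the (gaps x grid) kernel matrix stays modest
  chunk <- max(1L, floor(2e6 / length(gaps)))
  idx <- split(seq_along(grid), ceiling(seq_along(grid) / chunk))
  inten <- numeric(length(grid))
  for (ii in idx) {
    z <- outer(gaps, grid[ii], "-") / w
    inten[ii] <- norm * drop(crossprod(wt, exp(-z * z)))
  }
  nea_spectrum(grid, inten, w = w, metadata = metadata)
}

#' Locate the band maximum and shift of a spectrum
#'
#' Takes the grid argmax and refines it with a parabola through the argmax
#' and its two neighbours (exact for a Gaussian peak sampled near its top).
#' Ties are broken toward lower energy. The shift `delta = E_v - E_max`
#' (positive when the band maximum is redshifted below the vertical
#' excitation) is reported when a vertical energy is available, either as
#' the `E_v` argument or in the spectrum metadata.
#'
#' @param spectrum a [nea_spectrum()] with at least 3 points.
#' @param E_v vertical excitation energy (eV); default
#'   `spectrum$metadata$E_v`.
#' @return object of class `band_maximum`: list with `E_max` (eV),
#'   `shift_delta` (eV or NA), and `refinement`.
#' @export
band_maximum <- function(spectrum, E_v = NULL) {
  stopifnot(inherits(spectrum, "nea_spectrum"))
  E <- spectrum$energies; I <- spectrum$intensities
  if (length(E) < 3L) stop("need at least 3 grid points")
  if (diff(range(I)) == 0) stop("no unique maximum: spectrum is flat")
  i <- which.max(I)  # which.max takes the first (lowest-energy) tie
  refinement <- "grid"
  E_max <- E[i]
  if (i > 1L && i < length(E)) {
    y <- I[(i - 1L):(i + 1L)]
    denom <- y[1] - 2 * y[2] + y[3]
    if (denom < 0) {  # genuine local curvature; refine
      h_l <- E[i] - E[i - 1L]; h_r <- E[i + 1L] - E[i]
      d1 <- y[1] - y[2]; d3 <- y[3] - y[2]
      # vertex of the parabola through three (possibly unevenly spaced) points
      E_max <- E[i] + 0.5 * (d1 * h_r^2 - d3 * h_l^2) / (d1 * h_r + d3 * h_l)
      refinement <- "parabolic"
    }
  }
  E_v <- E_v %||% spectrum$metadata$E_v
  structure(list(E_max = E_max,
                 shift_delta = if (is.null(E_v)) NA_real_ else E_v - E_max,
                 refinement = refinement),
            class = "band_maximum")
}

#' @export
print.band_maximum <- function(x, ...) {
  cat(sprintf("Band maximum: E_max = %.4f eV (%s refinement)\n",
              x$E_max, x$refinement))
  if (is.finite(x$shift_delta))
    cat(sprintf("  shift delta = E_v - E_max = %+.4f eV\n", x$shift_delta))
  invisible(x)
}

#' Default photon-energy grid around a vertical excitation
#'
#' 2001 points spanning `[E_v - 2, E_v + 1]` eV (1.5 meV spacing).
#'
#' @param E_v centre energy (eV).
#' @param below,above extent of the grid below/above `E_v` (eV).
#' @param n_points number of grid points.
#' @return numeric grid (eV).
#' @export
default_grid <- function(E_v, below = 2, above = 1, n_points = 2001L) {
  seq(E_v - below, E_v + above, length.out = n_points)
}

#' Simulate a nuclear-ensemble spectrum and measure the band-maximum shift
#'
#' Composes [sample_positions()] (ground-state Wigner distribution),
#' [energy_gap()] per geometry, [mc_spectrum()] with uniform weights
#' (constant oscillator strength), and [band_maximum()]. The shift is
#' measured from the model's true vertical excitation, the gap at the
#' ground-state minimum.
#'
#' @param model a [two_state_model()].
#' @param n ensemble size (default 50000).
#' @param seed RNG seed.
#' @param w Gaussian line width (eV).
#' @param grid photon-energy grid (eV); default [default_grid()] around the
#'   vertical excitation.
#' @param keep_spectrum also return the simulated spectrum.
#' @return a [band_maximum()] (with the spectrum in `$spectrum` when
#'   `keep_spectrum`).
#' @export
measure_shift <- function(model, n = 50000L, seed = 1L, w = 0.05,
                          grid = NULL, keep_spectrum = FALSE) {
  E_v <- vertical_excitation(model)
  if (is.null(grid)) grid <- default_grid(E_v)
  q <- sample_positions(model, n, seed)
  gaps <- .ha2ev(energy_gap(model, unclass(q)))
  sp <- mc_spectrum(gaps, weights = NULL, grid = grid, w = w,
                    metadata = list(model = model$label, n = n,
                                    seed = attr(q, "seed"), E_v = E_v))
  bm <- band_maximum(sp)
  if (keep_spectrum) bm$spectrum <- sp
  bm
}
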