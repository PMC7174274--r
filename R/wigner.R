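#' Sample nuclear geometries from the ground-state Wigner distribution
#'
#' The position marginal of the zero-temperature harmonic-oscillator Wigner
#' distribution is, per mode, a Gaussian centred on the ground-state minimum
#' with variance `hbar / (2 mu omega_g)`. Modes are sampled independently;
#' momenta are not drawn because the semiclassical spectrum depends on
#' coordinates only.
#'
#' @param model a [two_state_model()].
#' @param n number of geometries (>= 1).
#' @param seed integer seed; the same seed and model give bit-identical
#'   samples (R's default Mersenne-Twister generator, recorded along with
#'   the seed in the result's attributes).
#' @return an `n x n_modes` matrix of coordinates in bohr (columns
#'   `mode_1`, `mode_2`, ...), class `wigner_samples`, with attributes
#'   `seed`, `rng_kind` and `model_label`.
#' @export
sample_positions <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "two_state_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive sample count")
  n <- as.integer(n)
  sd_q <- sqrt(1 / (2 * mode_field(model, "mu") * mode_field(model, "omega_g")))
  rng_kind <- "Mersenne-Twister"
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed), kind = rng_kind)
  q <- vapply(sd_q, function(s) stats::rnorm(n, 0, s), numeric(n))
  q <- matrix(q, nrow = n, dimnames = list(NULL, paste0("mode_", seq_along(sd_q))))
  structure(q, class = c("wigner_samples", "matrix", "array"),
            seed = as.integer(seed), rng_kind = rng_kind,
            model_label = model$label)
}

#' Wigner position density of a model
#'
#' Product over modes of the 1-D normalized Gaussians
#' `sqrt(alpha_r / pi) exp(-alpha_r q_r^2)` with `alpha_r = mu_r omega_{g,r}`
#' (atomic units, hbar = 1). For two degenerate modes this is
#' `(alpha / pi) exp(-alpha (q_1^2 + q_2^2))`.
#'
#' @inheritParams ground_energy
#' @return probability density per bohr^`n_modes` (one value per geometry).
#' @export
wigner_density <- function(model, q) {
  q <- .q_matrix(model, q)
  alpha <- mode_field(model, "mu") * mode_field(model, "omega_g")
  lognorm <- 0.5 * sum(log(alpha / pi))
  .drop1(drop(exp(lognorm - q^2 %*% alpha)))
}

#' Export sampled geometries as CSV
#'
#' One row per geometry, one column per mode (`mode_1`, ...), plain decimal
#' notation.
#'
#' @param samples a [sample_positions()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(samples, path) {
  utils::write.csv(as.data.frame(unclass(samples)), path, row.names = FALSE)
  invisible(path)
}
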