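# shared constants recomputed independently of the package internals
EV_PER_HARTREE <- 27.211386245988
HARTREE_PER_CM1 <- 1 / 219474.6313632
ME_PER_AMU <- 1822.888486209
CM1_TO_EV <- EV_PER_HARTREE * HARTREE_PER_CM1

# a small random multimode model for property-style checks
random_model <- function(n_modes = 3, seed = 1) {
  set.seed(seed)
  modes <- lapply(seq_len(n_modes), function(i)
    mode_spec(runif(1, 500, 2500), eta = runif(1, 0.3, 1.5),
              d = runif(1, -0.5, 0.5), mu = runif(1, 1, 12)))
  two_state_model(runif(1, 3, 7), modes)
}
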