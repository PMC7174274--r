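test_that("a single gap gives one normalized Gaussian line", {
  grid <- seq(3.5, 4.5, by = 0.001)
  sp <- mc_spectrum(4.08, grid = grid, w = 0.05,
                    metadata = list(E_v = 4.08))
  expect_equal(max(sp$intensities), 1 / (0.05 * sqrt(pi)), tolerance = 1e-6)
  bm <- band_maximum(sp)
  expect_equal(bm$E_max, 4.08, tolerance = 1e-9)
  expect_equal(bm$shift_delta, 0, tolerance = 1e-9)
  # line shapes are normalized: the spectrum integrates to one
  expect_equal(pracma::trapz(sp$energies, sp$intensities), 1,
               tolerance = 1e-6)
})

test_that("two close equal-weight gaps peak midway", {
  w <- 0.05; E0 <- 4; a <- 0.02  # a < w/sqrt(2): single maximum at E0
  grid <- seq(3.7, 4.3, by = 5e-4)
  sp <- mc_spectrum(c(E0 - a, E0 + a), grid = grid, w = w)
  # brute-force oracle: direct two-Gaussian sum on a 10x finer grid
  fine <- seq(3.7, 4.3, by = 5e-5)
  oracle <- 0.5 * (exp(-((fine - E0 + a) / w)^2) + exp(-((fine - E0 - a) / w)^2))
  expect_equal(band_maximum(sp)$E_max, fine[which.max(oracle)],
               tolerance = 5e-4)
  expect_equal(band_maximum(sp)$E_max, E0, tolerance = 1e-6)
})

test_that("parabolic refinement agrees with a much finer grid argmax", {
  p <- analytic_band_params(eta = 0.8, w = 0.05)
  coarse <- seq(3.9, 4.2, by = 2e-3)
  sp <- nea_spectrum(coarse, analytic_spectrum(p, coarse))
  fine <- seq(3.9, 4.2, by = 2e-4)
  ref <- fine[which.max(analytic_spectrum(p, fine))]
  expect_lt(abs(band_maximum(sp)$E_max - ref), 2e-3)  # within one spacing
})

test_that("degenerate two-mode simulation reproduces the first-order shift", {
  m2 <- model_degenerate_2mode(eta = 0.8)
  delta <- measure_shift(m2, n = 5e4, seed = 3, w = 0.05)$shift_delta
  expect_equal(delta, analytic_shift(1500, eta = 0.8), tolerance = 0.25)
  expect_gt(delta, 0)  # redshift for a softened excited state
})

test_that("spectrum construction rejects invalid inputs", {
  expect_error(mc_spectrum(numeric(0), grid = 1:10, w = 0.05), "nonempty")
  expect_error(mc_spectrum(4, grid = 1:10, w = 0), "positive")
  expect_error(mc_spectrum(4, weights = c(1, 2), grid = 1:10, w = 0.1),
               "length")
  expect_error(nea_spectrum(c(1, 1, 2), c(0, 0, 0)), "increasing")
  expect_error(nea_spectrum(1:3, c(0, -1, 0)), "nonnegative")
  flat <- nea_spectrum(seq(1, 2, by = 0.1), rep(1, 11))
  expect_error(band_maximum(flat), "no unique maximum")
  expect_error(band_maximum(nea_spectrum(1:2, c(0, 1))), "3 grid points")
})

test_that("uniform and jittered weights give the same shift", {
  # constant-oscillator-strength assumption: +-10% weight jitter is
  # irrelevant to the band maximum
  m2 <- model_degenerate_2mode(eta = 0.8)
  q <- sample_positions(m2, 5e4, seed = 21)
  gaps <- convert_unit(energy_gap(m2, unclass(q)), "hartree", "eV")
  grid <- default_grid(4.08)
  set.seed(99)
  jit <- runif(length(gaps), 0.9, 1.1)
  d_unif <- band_maximum(mc_spectrum(gaps, grid = grid, w = 0.05),
                         E_v = 4.08)$shift_delta
  d_jit <- band_maximum(mc_spectrum(gaps, weights = jit, grid = grid,
                                    w = 0.05), E_v = 4.08)$shift_delta
  expect_lt(abs(d_unif - d_jit), 0.005)
})

test_that("the single-mode band shows no shift at small width", {
  m <- model_1v(eta = 0.8)
  d_small <- measure_shift(m, n = 5e4, seed = 4, w = 0.01)$shift_delta
  expect_lt(abs(d_small), 0.005)
  # and the residual shift shrinks with the line width
  d_big <- measure_shift(m, n = 5e4, seed = 4, w = 0.1)$shift_delta
  expect_lt(abs(d_small), abs(d_big))
})

test_that("measure_shift is reproducible and records provenance", {
  m <- model_3v(eta2 = 0.8, d13 = 3)
  a <- measure_shift(m, n = 2e4, seed = 17, keep_spectrum = TRUE)
  b <- measure_shift(m, n = 2e4, seed = 17)
  expect_identical(a$shift_delta, b$shift_delta)
  expect_identical(a$spectrum$metadata$seed, 17L)
  expect_equal(a$spectrum$metadata$E_v, vertical_excitation(m))
})

test_that("spectra round-trip through CSV", {
  grid <- seq(3, 5, by = 0.01)
  sp <- mc_spectrum(c(3.9, 4.1), grid = grid, w = 0.1)
  path <- file.path(tempdir(), "spec.csv")
  write_spectrum_csv(sp, path)
  sp2 <- read_spectrum_csv(path)
  expect_equal(sp2$energies, sp$energies)
  expect_equal(sp2$intensities, sp$intensities, tolerance = 1e-12)
  unlink(path)
})
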