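test_that("the cross-section prefactor comes out of the fundamental constants", {
  expect_equal(cross_section_prefactor(), 0.619, tolerance = 1e-3)
  # the un-divided integral constant pi e^2 hbar / (2 m_e c eps0):
  # (pi/2) * (reduced Compton wavelength in A) * (e^2/eps0 in eV A)
  compton_A <- 3.8615926796e-3
  e2_over_eps0 <- 4 * pi * 14.3996454785  # Coulomb constant * 4pi, eV A
  expect_equal(cross_section_prefactor(integral = TRUE),
               pi / 2 * compton_A * e2_over_eps0, tolerance = 1e-9)
  expect_equal(cross_section_prefactor(integral = TRUE), 1.0975,
               tolerance = 1e-3)
  expect_equal(cross_section_prefactor() * sqrt(pi),
               cross_section_prefactor(integral = TRUE), tolerance = 1e-14)
})

test_that("convolution peaks, translates and integrates as it should", {
  grid <- seq(2, 8, by = 0.002)
  one <- convolve_subbands(subbands(5, 0.1, delta = 0, Gamma = 0.3), grid)
  i_pk <- which.max(one$intensities)
  expect_equal(grid[i_pk], 5, tolerance = 2e-3)
  expect_equal(max(one$intensities),
               cross_section_prefactor() * 0.1 / 0.3, tolerance = 1e-6)
  # a shift of 0.1 eV translates the same shape to lower energy
  shifted <- convolve_subbands(subbands(5, 0.1, delta = 0.1, Gamma = 0.3),
                               grid)
  keep <- grid >= 3 & grid <= 7
  approx_sh <- approx(grid - 0.1, one$intensities, xout = grid[keep])$y
  expect_equal(shifted$intensities[keep], approx_sh, tolerance = 1e-6)
  # empty band list: zero spectrum
  empty <- convolve_subbands(subbands(numeric(0), numeric(0)), grid)
  expect_true(all(empty$intensities == 0))
  expect_error(convolve_subbands(data.frame(E_v = 5, f = 1, delta = 0,
                                            Gamma = -1), grid), "Gamma")
})

test_that("sub-band areas are proportional to oscillator strengths", {
  set.seed(12)
  for (i in 1:5) {
    ns <- sample(1:4, 1)
    b <- subbands(runif(ns, 4, 7), runif(ns, 0.01, 1),
                  delta = runif(ns, -0.1, 0.3), Gamma = runif(ns, 0.1, 0.6))
    grid <- seq(min(b$E_v) - 6 * max(b$Gamma), max(b$E_v) + 6 * max(b$Gamma),
                by = 0.002)
    area <- pracma::trapz(grid, convolve_subbands(b, grid)$intensities)
    expect_equal(area, cross_section_prefactor(integral = TRUE) * sum(b$f),
                 tolerance = 1e-3)
  }
  # peak height follows f / Gamma, not f: same f, double width, half height
  g <- seq(3, 7, by = 0.002)
  h1 <- max(convolve_subbands(subbands(5, 0.2, 0, 0.2), g)$intensities)
  h2 <- max(convolve_subbands(subbands(5, 0.2, 0, 0.4), g)$intensities)
  expect_equal(h1 / h2, 2, tolerance = 1e-6)
})

test_that("fitting recovers noise-free sub-band parameters", {
  set.seed(5150)
  for (i in 1:10) {
    ns <- sample(1:3, 1)
    E_v <- seq(4, 7, length.out = ns + 1)[1:ns] + runif(ns, 0, 0.3)
    truth <- subbands(E_v, runif(ns, 0.02, 0.5),
                      delta = runif(ns, 0, 0.3), Gamma = runif(ns, 0.15, 0.6))
    grid <- seq(2.5, 8.5, by = 0.005)
    sp <- convolve_subbands(truth, grid)
    fit <- suppressWarnings(fit_subbands(sp, truth))
    expect_true(fit$converged)
    expect_lt(max(abs(fit$bands$delta - truth$delta)), 1e-6)
    expect_lt(max(abs(fit$bands$Gamma - truth$Gamma)), 1e-6)
    expect_lt(fit$residual_norm, 1e-8)
  }
})

test_that("a realizable single-Gaussian spectrum fits exactly", {
  grid <- seq(3, 8, by = 0.005)
  truth <- subbands(5.5, 0.1, delta = 0.12, Gamma = 0.35)
  fit <- fit_subbands(convolve_subbands(truth, grid), truth)
  expect_equal(fit$bands$delta, 0.12, tolerance = 1e-8)
  expect_equal(fit$bands$Gamma, 0.35, tolerance = 1e-8)
})

test_that("a three-band pyrimidine-like spectrum is recovered", {
  truth <- subbands(c(4.44, 5.52, 6.11), c(0.006, 0.030, 0.004),
                    delta = c(0.07, 0.11, 0.15),
                    Gamma = c(0.395, 0.262, 0.323))
  grid <- seq(3.5, 7.5, by = 0.005)
  fit <- fit_subbands(convolve_subbands(truth, grid), truth)
  expect_lt(max(abs(fit$bands$delta - truth$delta)), 1e-6)
  expect_lt(max(abs(fit$bands$Gamma - truth$Gamma)), 1e-6)
  # optimizing f as well still recovers everything
  fit_f <- fit_subbands(convolve_subbands(truth, grid), truth,
                        optimize_f = TRUE)
  expect_lt(max(abs(fit_f$bands$f - truth$f)), 1e-6)
})

test_that("fitted shifts survive 1% multiplicative noise", {
  truth <- subbands(c(4.8, 5.6), c(0.05, 0.2), delta = c(0.08, 0.15),
                    Gamma = c(0.3, 0.4))
  grid <- seq(3.5, 7, by = 0.01)
  clean <- convolve_subbands(truth, grid)
  errs <- replicate(20, {
    noisy <- nea_spectrum(grid, clean$intensities *
                            (1 + rnorm(length(grid), 0, 0.01)))
    fit <- fit_subbands(noisy, truth)
    max(abs(fit$bands$delta - truth$delta))
  })
  expect_lt(median(errs), 0.01)
})

test_that("fit input validation and estimator behave", {
  grid <- seq(4, 6, by = 1)
  truth <- subbands(c(4.5, 5.5), c(0.1, 0.2))
  expect_error(fit_subbands(convolve_subbands(truth, grid), truth),
               "fewer grid points")
  sp <- convolve_subbands(truth, seq(4.6, 5.4, by = 0.01))
  expect_error(fit_subbands(sp, subbands(c(3, 5), c(0.1, 0.1))),
               "does not cover")
  expect_identical(estimate_band_max(5.52), 5.42)
  expect_identical(estimate_band_max(4, delta_bar = 0), 4)
  expect_equal(estimate_band_max(6.3) - estimate_band_max(5.1), 1.2)
})
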