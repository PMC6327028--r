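test_that("a noiseless single-exponential matrix is fit exactly without IRF", {
  wl <- seq(400, 700, by = 50)
  d <- seq(0, 500, by = 10)
  spec <- exp(-((wl - 550) / 120)^2)
  A <- outer(spec, exp(-d / 100))
  m <- ta_matrix(wl, d, A)
  fit <- global_fit(m, 1, irf = NULL, offset = FALSE, init_taus = 60)
  expect_equal(fit$time_constants, 100, tolerance = 1e-3)
  expect_lt(fit$residual_rms, 1e-9)
})

test_that("the two solvation time constants are recovered from the seeded neat matrix", {
  m <- simulate_default_matrix(0, "ps", seed = 101)
  fit <- global_fit(m, 2, instrument_response(7))
  expect_true(fit$converged)
  expect_within(fit$time_constants[1], 45, 15)
  expect_within(fit$time_constants[2], 80, 30)
  # reconstruction residual close to the injected noise level
  expect_lt(fit$residual_rms, 1.1 * 5e-4)
  # decay-associated spectra: IR band decays (positive DAS in the IR for the
  # fast component), visible band rises with the blue shift
  ir_rows <- which(m$wavelengths >= 950)
  expect_gt(mean(fit$das[ir_rows, 1], na.rm = TRUE), 0)
})

test_that("variable projection agrees with a brute-force joint fit", {
  # 3 wavelengths x 20 delays, two components, modest noise
  wl <- c(450, 600, 950)
  d <- seq(0, 380, by = 20)
  DAS <- rbind(c(0.012, -0.004), c(0.008, 0.006), c(0.015, 0.001))
  B <- cbind(exp(-d / 45), exp(-d / 150))
  Y <- DAS %*% t(B) +
    withr::with_seed(9, matrix(rnorm(3 * length(d), 0, 1e-4), 3))
  m <- ta_matrix(wl, d, Y)
  fit <- global_fit(m, 2, irf = NULL, offset = FALSE, init_taus = c(30, 200))
  oracle <- brute_joint_fit(Y, d, 2, c(30, 200))
  expect_equal(fit$time_constants, oracle, tolerance = 5e-3)
})

test_that("fitted time constants are stable under 2x wavelength subsampling", {
  m <- simulate_default_matrix(0, "ps", seed = 55)
  sub <- ta_matrix(m$wavelengths[c(TRUE, FALSE)], m$delays,
                   m$absorbance[c(TRUE, FALSE), ],
                   mask = m$mask[c(TRUE, FALSE)])
  f1 <- global_fit(m, 2, instrument_response(7))
  f2 <- global_fit(sub, 2, instrument_response(7))
  expect_equal(f1$time_constants, f2$time_constants, tolerance = 0.10)
})

test_that("noise leaves the time constants unbiased within Monte-Carlo error", {
  taus <- t(sapply(1:12, function(s) {
    m <- small_matrix(0, seed = 300 + s,
                      wavelengths = seq(370, 1100, by = 20))
    global_fit(m, 2, instrument_response(7))$time_constants
  }))
  se <- apply(taus, 2, sd) / sqrt(nrow(taus))
  expect_within(mean(taus[, 1]), 45, 2 * max(se[1], 1))
  expect_within(mean(taus[, 2]), 80, 2 * max(se[2], 2))
})

test_that("global fit contract violations are rejected", {
  m <- small_matrix(0, seed = 1)
  expect_error(global_fit(m, 0), "n_components")
  expect_error(global_fit(m, 2, init_taus = 50), "length")
  tiny <- ta_matrix(c(400, 500), c(0, 10), matrix(1, 2, 2))
  expect_error(global_fit(tiny, 2), "delays")
})
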