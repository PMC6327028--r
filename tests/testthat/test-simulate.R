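test_that("noiseless bilinear matrices have exact rank equal to the active species count", {
  # neat solvent: three electron species populated, no anions
  m <- small_matrix(0, noise_sd = 0)
  sv <- svd(m$absorbance[!m$mask, ])$d
  expect_gt(sv[3] / sv[1], 1e-10)
  expect_lt(sv[4] / sv[1], 1e-10)
  # solution: all five species carry population
  m5 <- small_matrix(0.3, noise_sd = 0)
  sv5 <- svd(m5$absorbance[!m5$mask, ])$d
  expect_gt(sv5[5] / sv5[1], 1e-12)
  expect_lt(sv5[6] / sv5[1], 1e-10)
})

test_that("shifting mode reproduces the ~120 nm blue shift of the visible band", {
  m <- small_matrix(0, noise_sd = 0, mode = "shifting",
                    wavelengths = seq(370, 1100, by = 5),
                    delays = seq(-20, 500, by = 2))
  win <- which(!m$mask & m$wavelengths >= 550 & m$wavelengths <= 900)
  argmax_at <- function(t) {
    j <- which.min(abs(m$delays - t))
    m$wavelengths[win][which.max(m$absorbance[win, j])]
  }
  # earliest delay where the grown visible band dominates the window is
  # ~10 ps; its center there is ~736 nm, so the raw argmax shift is ~-106
  shift <- argmax_at(500) - argmax_at(10)  # >= 5 tau2 vs just after the pulse
  expect_within(shift, -110, 15)
  expect_equal(argmax_at(500), 630)
})

test_that("identical seeds give bitwise-identical matrices", {
  a <- small_matrix(0.1, seed = 77)
  b <- small_matrix(0.1, seed = 77)
  expect_identical(a$absorbance, b$absorbance)
  c <- small_matrix(0.1, seed = 78)
  expect_false(identical(a$absorbance, c$absorbance))
})

test_that("injected noise has the requested standard deviation", {
  noiseless <- small_matrix(0, noise_sd = 0,
                            wavelengths = seq(370, 1100, by = 5))
  noisy <- small_matrix(0, noise_sd = 5e-4, seed = 3,
                        wavelengths = seq(370, 1100, by = 5))
  resid <- (noisy$absorbance - noiseless$absorbance)[!noisy$mask, ]
  expect_gt(length(resid), 1e4)
  expect_within(sd(resid), 5e-4, 0.05 * 5e-4)
})

test_that("masked detector rows are sentinel-valued in every mode", {
  for (mode in c("bilinear", "shifting")) {
    m <- small_matrix(0.3, seed = 1, mode = mode,
                      wavelengths = seq(370, 1100, by = 5))
    blocked <- m$wavelengths >= 770 & m$wavelengths <= 790
    expect_identical(m$mask, blocked)
    expect_true(all(is.na(m$absorbance[blocked, ])))
    expect_true(all(is.finite(m$absorbance[!blocked, ])))
  }
})

test_that("absorbance scales linearly with dose", {
  s <- kinetic_scheme(concentration = 0)
  m1 <- simulate_ta_matrix(s, wavelengths = small_wavelengths(),
                           delays = small_delays(), noise_sd = 0)
  m2 <- simulate_ta_matrix(s, wavelengths = small_wavelengths(),
                           delays = small_delays(), noise_sd = 0,
                           dose = 50.6)
  expect_equal(m2$absorbance, m1$absorbance * 2, tolerance = 1e-12)
})

test_that("generator contract violations are rejected", {
  s <- kinetic_scheme()
  expect_error(simulate_ta_matrix(s, mode = "quadratic"), "arg")
  bad_bands <- default_bands()[1:3]
  expect_error(simulate_ta_matrix(s, bands = bad_bands), "one band per species")
  expect_error(simulate_ta_matrix(s, noise_sd = -1), "noise_sd")
})
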