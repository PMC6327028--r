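test_that("subtracting the neat matrix from itself leaves only noise", {
  a <- small_matrix(0, seed = 21)
  b <- small_matrix(0, seed = 22)
  sub <- subtract_reference(a, b)
  resid <- sub$isolated$absorbance[!sub$isolated$mask, ]
  expect_lt(sqrt(mean(resid^2)), 5e-4 * sqrt(2) * 1.1)
  # isolated values inside the matching window average to ~0
  rows <- !a$mask & a$wavelengths >= 900 & a$wavelengths <= 1000
  expect_lt(abs(mean(sub$isolated$absorbance[rows, ])), 5e-5)
})

test_that("the early-time scale factor equals the surviving electron fraction", {
  sol <- small_matrix(0.3, seed = 31)
  neat <- small_matrix(0, seed = 32)
  sub <- subtract_reference(sol, neat)
  early <- which(sol$delays >= 8 & sol$delays <= 30)
  # brute-force expectation from regenerated populations: every electron
  # species scales by exp(-C/c37), so the window ratio is that fraction
  s <- kinetic_scheme(concentration = 0.3)
  expected <- exp(-0.3 / s$c37)
  expect_within(mean(sub$scale_factors[early]), expected, 0.02)
})

test_that("the isolated excited-anion kinetics recover tau_tni", {
  sol <- simulate_default_matrix(0.3, "ps", seed = 41)
  neat <- simulate_default_matrix(0, "ps", seed = 42)
  sub <- subtract_reference(sol, neat)
  kin <- band_integrate(sub$isolated, c(370, 600))
  le <- estimate_lifetime_loglinear(sol$delays, kin, c(20, 500))
  expect_within(le$tau, 350, 0.15 * 350)
})

test_that("subtraction and MCR routes agree on the excited-anion lifetime", {
  sol <- simulate_default_matrix(0.3, "ps", seed = 41)
  neat <- simulate_default_matrix(0, "ps", seed = 42)
  sub <- subtract_reference(sol, neat)
  tau_sub <- estimate_lifetime_loglinear(
    sol$delays, band_integrate(sub$isolated, c(370, 600)), c(20, 500))$tau

  dec <- simulate_deconvolution_matrix(0.3, seed = 43)
  neat_us <- simulate_default_matrix(0, "us", seed = 44)
  esol_spec <- mean_spectrum(neat_us, c(5e5, 2e6))
  mc <- mcr_als(dec, 3, fixed_spectra = list(index = 3, spectrum = esol_spec))
  truth <- simulate_populations(kinetic_scheme(concentration = 0.3),
                                dec$delays)
  mt <- match_components(t(mc$profiles),
                         t(truth[c("rt_excited", "rt_ground", "e_sol"), ]))
  tau_mcr <- estimate_lifetime_loglinear(
    dec$delays, mc$profiles[mt$permutation[1], ], c(300, 1000))$tau
  expect_lt(abs(tau_sub - tau_mcr) / tau_sub, 0.20)
})

test_that("grid mismatches and bad windows are rejected", {
  a <- small_matrix(0, seed = 1)
  b <- small_matrix(0, seed = 2, delays = seq(-20, 500, by = 8))
  expect_error(subtract_reference(a, b), "share both grids")
  expect_error(subtract_reference(a, a, ir_window = c(600, 1000)),
               "720-1000")
})
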