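test_that("an exact exponential series is fit to machine precision", {
  conc <- c(0, 0.05, 0.1, 0.2, 0.3, 0.5)
  A <- 0.004 * exp(-conc / 0.37)
  model <- fit_scavenging(conc, A)
  expect_equal(model$c37, 0.37, tolerance = 1e-3)
  expect_equal(model$a0, 0.004, tolerance = 1e-6)
  expect_equal(model$r_squared, 1, tolerance = 1e-9)
})

test_that("single-anchor scavenging capacities match the closed-form roots", {
  # 1 - exp(-0.05/c37) = 0.12  and  1 - exp(-0.5/c37) = 0.75, solved
  # independently by uniroot
  r1 <- uniroot(function(c37) 1 - exp(-0.05 / c37) - 0.12,
                c(0.1, 2), tol = 1e-12)$root
  r2 <- uniroot(function(c37) 1 - exp(-0.5 / c37) - 0.75,
                c(0.1, 2), tol = 1e-12)$root
  expect_equal(-0.05 / log(0.88), r1, tolerance = 1e-9)
  expect_within(r1, 0.391, 0.391 * 0.005)
  expect_within(r2, 0.361, 0.361 * 0.005)
  # the generator default 0.37 lies between the two anchors
  expect_true(r2 < 0.37 && 0.37 < r1)
})

test_that("the synthetic concentration series reproduces the 12%/75% capture fractions", {
  conc <- c(0, 0.05, 0.1, 0.2, 0.3, 0.5)
  a0 <- vapply(seq_along(conc), function(i)
    initial_absorbance(simulate_default_matrix(conc[i], "ps", seed = 60 + i),
                       window = c(720, 1000)),
    numeric(1))
  model <- fit_scavenging(conc, a0)
  expect_within(100 * capture_fraction(model, 0.05), 12, 2)
  expect_within(100 * capture_fraction(model, 0.5), 75, 2)
  # direct amplitude-ratio route agrees with the fitted route
  direct <- 100 * (1 - a0 / a0[1])
  expect_within(direct[2], 12, 3)
  expect_within(direct[6], 75, 3)
})

test_that("fit_scavenging is scale-equivariant", {
  conc <- c(0, 0.05, 0.15, 0.3, 0.5)
  withr::with_seed(5, {
    A <- 0.004 * exp(-conc / 0.37) * exp(rnorm(5, 0, 0.02))
  })
  m1 <- fit_scavenging(conc, A)
  m2 <- fit_scavenging(conc, A * 7.5)
  expect_equal(m2$c37, m1$c37, tolerance = 1e-9)
  expect_equal(m2$a0, m1$a0 * 7.5, tolerance = 1e-9)
})

test_that("scavenging-time arithmetic follows the reciprocal law", {
  expect_equal(scavenging_time(5e12, 0.5), 4e-13)
  expect_equal(scavenging_time(5e12, 0.05), 4e-12)
  expect_equal(scavenging_time(5e12, 1), scavenging_time(5e12, 0.5) / 2)
  expect_error(scavenging_time(-1, 0.5), "positive")
})

test_that("yield curves sum to one and capture fractions behave at the limits", {
  yc <- yield_curve(0.37, c(0, 0.05, 0.5, 5))
  expect_equal(yc$relative_yield + yc$capture_fraction, rep(1, 4))
  expect_equal(capture_fraction(0.37, 0), 0)
  expect_equal(capture_fraction(0.391, 0.05), 0.120, tolerance = 1e-3)
  expect_equal(capture_fraction(0.361, 0.5), 0.750, tolerance = 1e-3)
  expect_error(capture_fraction(0.37, -1), "negative")
})

test_that("normalized IR kinetics are shape-invariant across the series", {
  wl <- seq(720, 1000, by = 5)
  mats <- lapply(seq_along(c(0.05, 0.1, 0.3, 0.5)), function(i) {
    small_matrix(c(0.05, 0.1, 0.3, 0.5)[i], seed = 70 + i,
                 wavelengths = wl, delays = seq(-20, 500, by = 2))
  })
  cmp <- normalized_kinetics_compare(mats, c(720, 1000))
  # empirical null (pure noise on identical kinetics) sits near 0.017 with
  # the default smoothing; any real shape change at these kinetics exceeds
  # 0.05, so the invariance bound is placed between the two
  expect_lt(cmp$max_deviation, 0.05)
  # identical matrices: exactly zero
  cmp0 <- normalized_kinetics_compare(list(mats[[1]], mats[[1]]))
  expect_equal(cmp0$max_deviation, 0)
})

test_that("a concentration-dependent tau1 is detected as a shape change", {
  wl <- seq(720, 1000, by = 5)
  concs <- c(0.05, 0.5)
  n_mc <- 60
  null_dev <- numeric(n_mc)
  alt_dev <- numeric(n_mc)
  for (s in seq_len(n_mc)) {
    null_mats <- lapply(1:2, function(i)
      small_matrix(concs[i], seed = 1000 * s + i, wavelengths = wl,
                   delays = seq(-20, 500, by = 2)))
    alt_mats <- lapply(1:2, function(i)
      small_matrix(concs[i], seed = 1000 * s + i, wavelengths = wl,
                   delays = seq(-20, 500, by = 2),
                   tau1 = 45 * (1 + 0.5 * concs[i])))
    null_dev[s] <- normalized_kinetics_compare(null_mats,
                                               smooth_window = 15)$max_deviation
    alt_dev[s] <- normalized_kinetics_compare(alt_mats,
                                              smooth_window = 15)$max_deviation
  }
  # the perturbed series exceeds the null 95th percentile almost always
  thr <- quantile(null_dev, 0.95)
  expect_gte(mean(alt_dev > thr), 0.95)
})

test_that("new-species amplitudes are linear in the electrons captured", {
  conc <- c(0, 0.05, 0.1, 0.2, 0.3, 0.5)
  cf <- capture_fraction(0.37, conc)
  # perfectly proportional inputs
  lin <- amplitude_linearity(0.02 * cf, cf)
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)
  expect_equal(lin$intercept, 0, tolerance = 1e-12)
  # generator series: initial isolated UV amplitude vs capture fraction
  amps <- vapply(seq_along(conc), function(i) {
    sol <- small_matrix(conc[i], seed = 80 + i)
    neat <- small_matrix(0, seed = 90 + i)
    iso <- subtract_reference(sol, neat)$isolated
    mean(band_integrate(iso, c(370, 600))[sol$delays >= 8 & sol$delays <= 16])
  }, numeric(1))
  lin2 <- amplitude_linearity(amps, cf)
  expect_gte(lin2$r_squared, 0.99)
  expect_lt(abs(lin2$intercept), 2 * lin2$intercept_se)
  # permutation null: shuffled pairing destroys the correlation
  withr::with_seed(7, {
    hits <- sum(vapply(1:100, function(i) {
      amplitude_linearity(amps, sample(cf))$r_squared < 0.5
    }, logical(1)))
  })
  expect_gte(hits, 85)
})
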