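test_that("rank estimation finds the exact bilinear rank and the early-time rank", {
  # neat ps window: three electron species
  expect_equal(estimate_rank(small_matrix(0, noise_sd = 0))$rank, 3L)

  # high concentration, fast relaxation already complete, ground anion not
  # yet formed: only the solvated electron and the excited anion rise above
  # the noise floor at early times
  s <- kinetic_scheme(tau1 = 2, tau2 = 3, concentration = 0.5)
  m <- simulate_ta_matrix(s, wavelengths = seq(370, 1100, by = 5),
                          delays = seq(10, 300, by = 2), irf = NULL,
                          noise_sd = 5e-4, seed = 6)
  expect_equal(estimate_rank(m)$rank, 2L)

  expect_error(estimate_rank(matrix(0, 4, 4)), "all-zero")
})

test_that("pure-noise matrices are assigned rank <= 1 in at least 95 of 100 seeds", {
  hits <- sum(vapply(1:100, function(s) {
    A <- withr::with_seed(s, matrix(rnorm(60 * 80, 0, 5e-4), 60, 80))
    estimate_rank(A)$rank <= 1
  }, logical(1)))
  expect_gte(hits, 95)
})

test_that("purest-variable selection lands inside separable band supports", {
  # two non-overlapping Gaussian bands with distinct kinetics
  wl <- seq(370, 1100, by = 10)
  d <- seq(0, 200, by = 5)
  s1 <- make_species_spectrum(spectral_band(450, 80, 0.02), wl)
  s2 <- make_species_spectrum(spectral_band(900, 80, 0.02), wl)
  A <- outer(s1, exp(-d / 50)) + outer(s2, exp(-d / 500))
  m <- ta_matrix(wl, d, A)
  pv <- initialize_purest_variables(m, 2)
  expect_true(all(abs(pv$wavelengths - 450) < 120 |
                    abs(pv$wavelengths - 900) < 120))
  expect_equal(sum(abs(pv$wavelengths - 450) < 120), 1)

  # rank 1: contract definition of the first pick
  pv1 <- initialize_purest_variables(m, 1)
  ok <- which(!m$mask)
  mu <- rowMeans(A[ok, ]); sdv <- apply(A[ok, ], 1, sd)
  crit <- mu / (sdv + 0.05 * max(mu))
  expect_equal(pv1$indices, ok[which.max(crit)])
})

test_that("delay-direction initial spectra correlate with the true spectra", {
  m <- simulate_deconvolution_matrix(0.3, seed = 11)
  pv <- initialize_purest_variables(m, 3, direction = "delay")
  truth <- vapply(default_bands()[c("rt_excited", "rt_ground", "e_sol")],
                  make_species_spectrum, numeric(length(m$wavelengths)),
                  wavelengths = m$wavelengths)
  mt <- match_components(pv$spectra, truth)
  # the solvated-electron and ground-anion epochs are nearly pure; the
  # earliest selected delay is an anion/electron mixture, so the matched
  # mean is the meaningful score
  expect_gte(mt$mean_correlation, 0.7)
  expect_gte(sort(mt$correlations, decreasing = TRUE)[2], 0.9)
})

test_that("MCR-ALS attains the global optimum from a truthful start", {
  # strictly three absorbing species: electron-relaxation bands switched off
  bands <- default_bands()
  bands$e_ir$amplitude <- 0
  bands$e_vis$amplitude <- 0
  delays <- 10^seq(log10(300), log10(3e5), length.out = 120)
  m <- simulate_ta_matrix(kinetic_scheme(concentration = 0.3), bands = bands,
                          delays = delays, noise_sd = 0)
  truth <- simulate_populations(kinetic_scheme(concentration = 0.3),
                                m$delays)
  tp <- truth[c("rt_excited", "rt_ground", "e_sol"), ]
  mc <- mcr_als(m, 3, init = tp)
  expect_lt(mc$lack_of_fit_trace[length(mc$lack_of_fit_trace)], 0.1)
  mt <- match_components(t(mc$profiles), t(tp))
  expect_gte(min(mt$correlations), 0.999)
  # scale/permutation are the only ambiguities: spectra match too
  st <- vapply(default_bands()[c("rt_excited", "rt_ground", "e_sol")],
               make_species_spectrum, numeric(length(m$wavelengths)),
               wavelengths = m$wavelengths)
  ms <- match_components(mc$spectra, st)
  expect_gte(min(ms$correlations), 0.999)
})

test_that("the ALS lack of fit never increases", {
  m <- simulate_deconvolution_matrix(0.3, seed = 8)
  mc <- mcr_als(m, 3, max_iter = 60, tol = 0)
  expect_true(all(diff(mc$lack_of_fit_trace) <= 1e-9))
  expect_false(mc$converged)   # tol = 0 can never be met: flagged, no error
})

test_that("each ALS half-step equals brute-force non-negative least squares", {
  withr::with_seed(13, {
    S_true <- matrix(runif(12), 6, 2)
    P_true <- matrix(runif(12), 2, 6)
    Y <- S_true %*% P_true + matrix(rnorm(36, 0, 0.02), 6, 6)
  })
  m <- ta_matrix(seq(400, 900, length.out = 6), seq(0, 50, length.out = 6), Y)
  # one profile half-step from fixed spectra
  mc <- mcr_als(m, 2, init = S_true, max_iter = 1, tol = 1e9)
  P_pkg <- mc$profiles
  # undo the unit-maximum rescaling to compare raw solutions
  scale <- apply(S_true, 2, max)
  P_raw <- P_pkg / scale
  P_oracle <- vapply(seq_len(6), function(j) brute_nnls(S_true, Y[, j]),
                     numeric(2))
  expect_equal(unname(P_raw), unname(P_oracle), tolerance = 1e-8)
})

test_that("the default seeded deconvolution separates the three late species", {
  m <- simulate_deconvolution_matrix(0.3, seed = 11)
  rk <- estimate_rank(m)
  expect_equal(rk$rank, 3L)
  mc <- mcr_als(m, 3)
  truth <- simulate_populations(kinetic_scheme(concentration = 0.3), m$delays)
  tp <- truth[c("rt_excited", "rt_ground", "e_sol"), ]
  mt <- match_components(t(mc$profiles), t(tp))
  expect_gte(mt$mean_correlation, 0.9)

  # solvated-electron spectrum peaks at the 630 nm band position
  esol <- mt$permutation[3]
  expect_within(m$wavelengths[which.max(mc$spectra[, esol])], 630, 10)

  # decay of the excited anion does not feed the ground anion: in the
  # known-species (fixed e_sol spectrum) variant, by 3 tau_tni the anion has
  # decayed > 90% while < 10% of the final ground-anion population exists
  esol_spec <- mean_spectrum(simulate_default_matrix(0, "us", seed = 12),
                             c(5e5, 2e6))
  mcf <- mcr_als(m, 3, fixed_spectra = list(index = 3, spectrum = esol_spec))
  mtf <- match_components(t(mcf$profiles), t(tp))
  exc <- mcf$profiles[mtf$permutation[1], ]
  gnd <- mcf$profiles[mtf$permutation[2], ]
  j3 <- which.min(abs(m$delays - 3 * 350))
  expect_lt(exc[j3] / max(exc), 0.10)
  expect_lt(gnd[j3] / max(gnd), 0.10)
})

test_that("component matching resolves permutations and scores similarity", {
  X <- matrix(rnorm(40), 10, 4)
  id <- match_components(X, X)
  expect_equal(id$permutation, 1:4)
  expect_equal(id$correlations, rep(1, 4))
  sw <- match_components(X[, c(2, 1, 4, 3)], X)
  expect_equal(sw$permutation, c(2, 1, 4, 3))
  expect_error(match_components(X, X[, 1:2]), "counts differ")
})
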