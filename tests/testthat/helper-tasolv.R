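# Shared fixtures and independent oracles for the test suite.

# Small grids keep simulation-heavy tests fast.
small_wavelengths <- function(step = 10) seq(370, 1100, by = step)
small_delays <- function(step = 4) seq(-20, 500, by = step)

small_matrix <- function(concentration = 0, seed = NULL, noise_sd = 5e-4,
                         mode = "bilinear", delays = small_delays(),
                         wavelengths = small_wavelengths(), ...) {
  simulate_ta_matrix(kinetic_scheme(concentration = concentration, ...),
                     wavelengths = wavelengths, delays = delays,
                     noise_sd = noise_sd, mode = mode, seed = seed)
}

# Independent oracle: non-negative least squares by brute-force active-set
# enumeration (all subsets of coefficients allowed to be positive).
brute_nnls <- function(C, d) {
  p <- ncol(C)
  best <- rep(0, p)
  best_rss <- sum(d^2)
  for (k in seq_len(2^p) - 1) {
    on <- which(bitwAnd(k, 2^(seq_len(p) - 1)) > 0)
    if (length(on) == 0) next
    x <- tryCatch(qr.solve(C[, on, drop = FALSE], d),
                  error = function(e) NULL)
    if (is.null(x) || any(x < -1e-12)) next
    full <- rep(0, p)
    full[on] <- pmax(x, 0)
    rss <- sum((d - C %*% full)^2)
    if (rss < best_rss - 1e-12) {
      best_rss <- rss
      best <- full
    }
  }
  best
}

# Independent oracle: joint nonlinear fit of taus and all amplitudes at once
# (no variable projection), for comparison with global_fit.
brute_joint_fit <- function(Y, delays, n_comp, start_taus) {
  n_wl <- nrow(Y)
  obj <- function(par) {
    taus <- exp(par[seq_len(n_comp)])
    A <- matrix(par[-seq_len(n_comp)], n_wl, n_comp)
    B <- vapply(taus, function(tau)
      as.numeric(delays >= 0) * exp(-pmax(delays, 0) / tau),
      numeric(length(delays)))
    sum((Y - A %*% t(B))^2)
  }
  B0 <- vapply(start_taus, function(tau)
    as.numeric(delays >= 0) * exp(-pmax(delays, 0) / tau),
    numeric(length(delays)))
  A0 <- t(qr.coef(qr(B0), t(Y)))
  fit <- stats::optim(c(log(start_taus), as.numeric(A0)), obj,
                      method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  sort(exp(fit$par[seq_len(n_comp)]))
}

# Independent oracle: kinetic-scheme populations by numerical ODE
# integration (deSolve), same state order as simulate_populations().
ode_populations <- function(scheme, delays) {
  k1 <- 1 / scheme$tau1
  k2 <- 1 / scheme$tau2
  k3 <- 1 / (scheme$tau_esol * 1e6) +
    scheme$k_esol_attach * 1e-12 * scheme$concentration
  kc <- scheme$k_esol_attach * 1e-12 * scheme$concentration
  ktni <- 1 / scheme$tau_tni
  u0 <- exp(-scheme$concentration / scheme$c37)
  rhs <- function(t, y, p) {
    list(c(-k1 * y[1],
           k1 * y[1] - k2 * y[2],
           k2 * y[2] - k3 * y[3],
           -ktni * y[4],
           kc * y[3]))
  }
  out <- deSolve::ode(y = c(u0, 0, 0, 1 - u0, 0), times = c(0, pmax(delays, 0)),
                      func = rhs, parms = NULL, rtol = 1e-10, atol = 1e-12)
  pop <- t(out[-1, -1, drop = FALSE])
  pop * rep(as.numeric(delays >= 0), each = 5)
}

expect_within <- function(object, target, tol) {
  expect_true(abs(object - target) <= tol,
              label = sprintf("%.6g (target %.6g +/- %.3g)",
                              object, target, tol))
}
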