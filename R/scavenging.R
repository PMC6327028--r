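#' Fit the exponential electron-scavenging law
#'
#' Least-squares fit of `A(C) = a0 * exp(-C / c37)` to initial near-IR
#' absorbances over a concentration series.  The fit is performed on
#' `ln A` versus `C` with weights proportional to the absorbance, which
#' linearizes the exponential while approximating unweighted least squares on
#' the linear scale.
#'
#' @param concentrations Solute concentrations, mol/L (>= 3 distinct values,
#'   at least one near zero).
#' @param initial_absorbances Matching initial absorbances, OD (> 0).
#' @param k_pre Pre-solvated-electron scavenging rate constant carried as
#'   model metadata, L mol^-1 s^-1 (not fitted).
#' @return Object of class `scavenging_model` with `c37` (mol/L), `a0` (OD),
#'   `k_pre`, `r_squared`, `fitted`.
#' @export
fit_scavenging <- function(concentrations, initial_absorbances,
                           k_pre = 5e12) {
  if (length(concentrations) != length(initial_absorbances))
    stop("input lengths differ", call. = FALSE)
  if (length(unique(concentrations)) < 3)
    stop("need at least 3 distinct concentrations", call. = FALSE)
  if (min(concentrations) > 0.2 * max(concentrations))
    stop("need at least one concentration near zero", call. = FALSE)
  if (any(initial_absorbances <= 0))
    stop("absorbances must be positive", call. = FALSE)
  fit <- stats::lm(log(initial_absorbances) ~ concentrations,
                   weights = initial_absorbances)
  slope <- stats::coef(fit)[["concentrations"]]
  if (slope >= 0)
    stop("absorbance does not decrease with concentration", call. = FALSE)
  structure(list(c37 = -1 / slope,
                 a0 = exp(stats::coef(fit)[["(Intercept)"]]),
                 k_pre = k_pre,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 fitted = exp(stats::fitted(fit))),
            class = "scavenging_model")
}

#' @export
print.scavenging_model <- function(x, ...) {
  cat(sprintf(
    "<scavenging_model> c37 %.4g M | a0 %.4g OD | k_pre %.3g /M/s | R^2 %.4f\n",
    x$c37, x$a0, x$k_pre, x$r_squared))
  invisible(x)
}

#' Fraction of electrons captured within the pulse
#'
#' `1 - exp(-c / c37)`: monotone in `c`, 0 at zero concentration, 1 in the
#' limit of infinite scavenger.
#'
#' @param model A [fit_scavenging()] result, or a bare `c37` value (mol/L).
#' @param c Concentration(s), mol/L (>= 0).
#' @return Capture fraction(s) in \[0, 1\].
#' @export
capture_fraction <- function(model, c) {
  c37 <- if (inherits(model, "scavenging_model")) model$c37 else model
  if (any(c < 0)) stop("negative concentration", call. = FALSE)
  1 - exp(-c / c37)
}

#' Mean scavenging time of the pre-solvated electron
#'
#' Pseudo-first-order competition arithmetic: `1 / (k * c)` seconds.
#'
#' @param k Rate constant, L mol^-1 s^-1 (> 0).
#' @param c Scavenger concentration, mol/L (> 0).
#' @return Time in seconds.
#' @export
scavenging_time <- function(k, c) {
  if (any(k <= 0) || any(c <= 0))
    stop("`k` and `c` must be positive", call. = FALSE)
  1 / (k * c)
}

#' Relative electron yield curve
#'
#' Tabulates the surviving (relative) electron yield `exp(-C/c37)` and the
#' complementary capture fraction across a concentration series; the two
#' columns sum to one by construction (asserted).
#'
#' @param model A [fit_scavenging()] result or bare `c37`.
#' @param concentrations Concentrations, mol/L.
#' @return `data.frame` with columns `concentration`, `relative_yield`,
#'   `capture_fraction`.
#' @export
yield_curve <- function(model, concentrations) {
  cf <- capture_fraction(model, concentrations)
  out <- data.frame(concentration = concentrations,
                    relative_yield = 1 - cf,
                    capture_fraction = cf)
  stopifnot(all(abs(out$relative_yield + out$capture_fraction - 1) < 1e-12))
  out
}

#' Compare normalized band kinetics across matrices
#'
#' Band-integrates each matrix over a wavelength window, smooths the traces
#' with a short boxcar (suppressing the white-noise contribution so the
#' statistic reflects kinetic shape rather than detector noise), normalizes
#' each trace to its own maximum, and returns the maximum pairwise RMS
#' difference between the normalized traces - the statistic behind the
#' observation that scavenging changes the amplitude but not the shape of
#' the pre-solvated electron kinetics.
#'
#' @param mats List of [ta_matrix()] objects sharing a delay grid.
#' @param window Wavelength window, nm.
#' @param smooth_window Boxcar width in delay points (odd; 1 disables).
#' @return List with `max_deviation`, `pairwise` (matrix of RMS differences)
#'   and `traces` (normalized kinetics, columns per matrix).
#' @export
normalized_kinetics_compare <- function(mats, window = c(720, 1000),
                                        smooth_window = 9) {
  if (length(mats) < 2)
    stop("need at least 2 matrices", call. = FALSE)
  d0 <- mats[[1]]$delays
  for (m in mats)
    if (!isTRUE(all.equal(m$delays, d0)))
      stop("matrices must share the delay grid", call. = FALSE)
  traces <- vapply(mats, function(m) {
    y <- band_integrate(m, window)
    if (smooth_window > 1) {
      k <- rep(1 / smooth_window, smooth_window)
      sm <- stats::filter(y, k, sides = 2)
      y <- ifelse(is.na(sm), y, as.numeric(sm))
    }
    y / max(y)
  }, numeric(length(d0)))
  n <- length(mats)
  pw <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    pw[i, j] <- pw[j, i] <- sqrt(mean((traces[, i] - traces[, j])^2))
  list(max_deviation = max(pw), pairwise = pw, traces = traces)
}

#' Linearity of new-species amplitude with electrons captured
#'
#' Ordinary least squares of the initial solute-species absorbance against
#' the capture fraction across a concentration series.
#'
#' @param initial_amplitudes Initial amplitudes of the new species, OD.
#' @param capture_fractions Matching capture fractions.
#' @return List with `slope`, `intercept`, `intercept_se`, `r_squared`.
#' @export
amplitude_linearity <- function(initial_amplitudes, capture_fractions) {
  if (length(initial_amplitudes) != length(capture_fractions) ||
      length(initial_amplitudes) < 3)
    stop("need >= 3 paired points", call. = FALSE)
  if (stats::sd(capture_fractions) == 0)
    stop("degenerate (constant) abscissa", call. = FALSE)
  fit <- stats::lm(initial_amplitudes ~ capture_fractions)
  sm <- suppressWarnings(summary(fit))
  list(slope = stats::coef(fit)[["capture_fractions"]],
       intercept = stats::coef(fit)[["(Intercept)"]],
       intercept_se = sm$coefficients["(Intercept)", "Std. Error"],
       r_squared = sm$r.squared)
}
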