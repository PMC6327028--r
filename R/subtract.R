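#' Isolate solute signals by neat-solvent reference subtraction
#'
#' In the near-IR window the absorbance comes only from the (pre-)solvated
#' electron, so for each delay a non-negative least-squares scalar matches
#' the neat-solvent matrix to the solution matrix over that window; the
#' isolated solute signal is `solution - scale * neat`.  At early delays the
#' scale factor approaches the surviving electron fraction
#' `exp(-C/c37)`.
#'
#' The true scale factor is a ratio of electron survival kinetics and varies
#' smoothly with delay, while its per-delay least-squares estimate becomes
#' noise-dominated once the near-IR signal has decayed; by default the raw
#' per-delay estimates are therefore smoothed by loess weighted with the
#' least-squares information (the window sum of squared neat absorbance).
#' Set `smooth_span = NULL` for the raw per-delay scalars.
#'
#' @param solution,neat [ta_matrix()] objects sharing both grids.
#' @param ir_window Matching window, nm, inside 720-1000 nm.
#' @param smooth_span Loess span for scale-factor smoothing, or `NULL` to
#'   disable.
#' @return Object of class `subtraction_result` with `isolated` (a
#'   [ta_matrix()] carrying the solution matrix's mask), `scale_factors`
#'   (per delay, >= 0), `scale_factors_raw`, `ir_window`.
#' @export
subtract_reference <- function(solution, neat, ir_window = c(900, 1000),
                               smooth_span = 0.35) {
  stopifnot(inherits(solution, "ta_matrix"), inherits(neat, "ta_matrix"))
  if (!isTRUE(all.equal(solution$wavelengths, neat$wavelengths)) ||
      !isTRUE(all.equal(solution$delays, neat$delays)))
    stop("solution and neat matrices must share both grids", call. = FALSE)
  if (ir_window[1] < 720 || ir_window[2] > 1000)
    stop("`ir_window` must lie within 720-1000 nm", call. = FALSE)
  rows <- which(!solution$mask & !neat$mask &
                  solution$wavelengths >= ir_window[1] &
                  solution$wavelengths <= ir_window[2])
  if (length(rows) == 0)
    stop("empty IR window after masking", call. = FALSE)

  n_t <- length(solution$delays)
  # Attenuation correction: noise in the neat (regressor) matrix inflates
  # sum(nv^2) by N*sigma^2 and biases the least-squares scalar low once the
  # near-IR signal decays; sigma is estimated from second differences along
  # the delay axis (variance 6*sigma^2 for white noise on a smooth signal).
  sigma2 <- stats::median(apply(neat$absorbance[rows, , drop = FALSE], 1,
                                function(x) {
                                  d2 <- diff(diff(x))
                                  stats::mad(d2)^2 / 6
                                }))
  scale_raw <- numeric(n_t)
  info <- numeric(n_t)
  for (j in seq_len(n_t)) {
    nv <- neat$absorbance[rows, j]
    sv <- solution$absorbance[rows, j]
    info[j] <- max(sum(nv^2) - length(nv) * sigma2, 0)
    scale_raw[j] <- if (info[j] > 0) max(0, sum(nv * sv) / info[j]) else 0
  }
  scale <- scale_raw
  if (!is.null(smooth_span) && n_t >= 10 && any(info > 0)) {
    fit <- stats::loess(scale_raw ~ solution$delays, weights = info,
                        span = smooth_span, degree = 2,
                        family = "gaussian", surface = "direct")
    scale <- pmax(0, stats::predict(fit, solution$delays))
  }
  iso <- solution$absorbance - neat$absorbance * rep(scale, each = nrow(neat$absorbance))
  iso[solution$mask | neat$mask, ] <- NA_real_
  isolated <- ta_matrix(solution$wavelengths, solution$delays, iso,
                        mask = solution$mask | neat$mask,
                        concentration = solution$concentration,
                        dose = solution$dose, seed = solution$seed,
                        mode = solution$mode)
  structure(list(isolated = isolated, scale_factors = scale,
                 scale_factors_raw = scale_raw, ir_window = ir_window),
            class = "subtraction_result")
}

#' @export
print.subtraction_result <- function(x, ...) {
  cat(sprintf(
    "<subtraction_result> window %0.f-%0.f nm | scale range %.3g-%.3g\n",
    x$ir_window[1], x$ir_window[2], min(x$scale_factors),
    max(x$scale_factors)))
  invisible(x)
}
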