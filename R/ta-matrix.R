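#' Transient absorption matrix
#'
#' Container for a wavelengths x delays absorbance matrix with detector mask
#' and experiment metadata.  Masked wavelength rows carry `NA` throughout and
#' are excluded from every analysis step in the package.
#'
#' @param wavelengths Strictly ascending wavelength grid, nm.
#' @param delays Strictly ascending delay grid, ps.
#' @param absorbance Numeric matrix, `length(wavelengths)` x `length(delays)`,
#'   optical-density units.
#' @param mask Logical vector per wavelength; `TRUE` marks detector-blocked
#'   rows.
#' @param concentration Solute concentration, mol/L.
#' @param dose Dose per pulse, Gy.
#' @param seed Integer seed used for the noise draw, or `NULL`.
#' @param mode Simulation mode the matrix came from (`"bilinear"`,
#'   `"shifting"`, or `"unknown"` for data read from disk).
#' @return Object of class `ta_matrix`.
#' @export
ta_matrix <- function(wavelengths, delays, absorbance,
                      mask = rep(FALSE, length(wavelengths)),
                      concentration = 0, dose = 25.3, seed = NULL,
                      mode = "unknown") {
  if (any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly ascending", call. = FALSE)
  if (any(diff(delays) <= 0))
    stop("delay grid must be strictly ascending", call. = FALSE)
  absorbance <- as.matrix(absorbance)
  if (!all(dim(absorbance) == c(length(wavelengths), length(delays))))
    stop("absorbance dimensions must match the grids", call. = FALSE)
  if (length(mask) != length(wavelengths))
    stop("mask length must match the wavelength grid", call. = FALSE)
  if (any(!is.finite(absorbance[!mask, , drop = FALSE])))
    stop("absorbance must be finite on unmasked rows", call. = FALSE)
  absorbance[mask, ] <- NA_real_
  structure(list(wavelengths = as.numeric(wavelengths),
                 delays = as.numeric(delays),
                 absorbance = absorbance, mask = as.logical(mask),
                 concentration = concentration, dose = dose,
                 seed = seed, mode = mode),
            class = "ta_matrix")
}

#' @export
print.ta_matrix <- function(x, ...) {
  cat(sprintf(
    "<ta_matrix> %d wavelengths (%.0f-%.0f nm, %d masked) x %d delays (%.4g-%.4g ps)\n",
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    sum(x$mask), length(x$delays), min(x$delays), max(x$delays)))
  cat(sprintf("  mode %s | C = %.3g M | dose %.3g Gy | seed %s\n",
              x$mode, x$concentration, x$dose,
              if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}

#' Default experiment grids
#'
#' Picosecond mode covers -20 to 500 ps in 2 ps steps (the pump-probe window);
#' microsecond mode covers 0.01 to 20 us with 200 log-spaced points, stored in
#' ps so all delay axes share one unit.
#'
#' @param mode `"ps"` or `"us"`.
#' @return Numeric delay grid in ps.
#' @export
default_delays <- function(mode = c("ps", "us")) {
  mode <- match.arg(mode)
  if (mode == "ps") seq(-20, 500, by = 2)
  else 10^seq(log10(1e4), log10(2e7), length.out = 200)
}

#' @rdname default_delays
#' @export
default_wavelengths <- function() seq(370, 1100, by = 5)

#' Default species bands
#'
#' One band per cascade species, in the fixed [species_names()] order: a broad
#' near-IR band for the unrelaxed electron, a 750 nm hot-visible band, the
#' 630 nm solvated-electron band, a UV-peaked excited-anion band (400 nm) and
#' a ground-anion band (520 nm).  Centers of the anion bands and all widths
#' are generator defaults chosen for spectral distinguishability; amplitudes
#' set the optical-density scale of the simulated experiment.
#'
#' @return Named list of [spectral_band()] objects.
#' @export
default_bands <- function() {
  list(e_ir       = spectral_band(1150, 300, 0.012),
       e_vis      = spectral_band(750, 300, 0.020),
       e_sol      = spectral_band(630, 350, 0.020),
       rt_excited = spectral_band(400, 150, 0.015),
       rt_ground  = spectral_band(520, 140, 0.015))
}

#' Default detector mask window
#' @return Length-2 numeric vector, nm.
#' @export
default_mask_window <- function() c(770, 790)

#' Simulate a transient absorption matrix
#'
#' Builds the noiseless signal from the kinetic scheme and species bands,
#' convolves every wavelength trace with the instrument response (when the
#' delay grid is uniform; on log-spaced microsecond grids the 7 ps response is
#' negligible and convolution is skipped), adds i.i.d. Gaussian noise, and
#' applies the detector mask.
#'
#' In `bilinear` mode the matrix is the exact bilinear product of static
#' species spectra and populations.  In `shifting` mode the visible-electron
#' population (`e_vis + e_sol`) is rendered as a single band whose center
#' follows `lambda(t) = lambda_final + (lambda_initial - lambda_final) *
#' exp(-t/tau2)`, reproducing the continuous blue shift of the relaxing
#' electron; all other species remain static.
#'
#' @param scheme A [kinetic_scheme()].
#' @param bands Named list of one [spectral_band()] per species, in
#'   [species_names()] order.
#' @param irf An [instrument_response()] or `NULL` to skip broadening.
#' @param wavelengths,delays Grids (nm, ps).
#' @param noise_sd Additive noise standard deviation, OD.
#' @param mode `"bilinear"` or `"shifting"`.
#' @param seed Integer seed for the noise draw (`NULL` for the current RNG
#'   state).  Identical seeds give bitwise-identical matrices.
#' @param dose Dose per pulse, Gy; amplitudes scale linearly with
#'   `dose / 25.3`.
#' @param mask_window Detector-blocked wavelength interval, nm, or `NULL`.
#' @return A [ta_matrix()].
#' @export
simulate_ta_matrix <- function(scheme, bands = default_bands(),
                               irf = instrument_response(),
                               wavelengths = default_wavelengths(),
                               delays = default_delays("ps"),
                               noise_sd = 5e-4,
                               mode = c("bilinear", "shifting"),
                               seed = NULL, dose = 25.3,
                               mask_window = default_mask_window()) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  sp <- species_names()
  if (!identical(sort(names(bands)), sort(sp)))
    stop("`bands` must be a named list with exactly one band per species: ",
         paste(sp, collapse = ", "), call. = FALSE)
  bands <- bands[sp]

  pop <- simulate_populations(scheme, delays)
  n_wl <- length(wavelengths); n_t <- length(delays)

  if (mode == "bilinear") {
    S <- vapply(sp, function(s) make_species_spectrum(bands[[s]], wavelengths),
                numeric(n_wl))
    A <- S %*% pop
  } else {
    static <- c("e_ir", "rt_excited", "rt_ground")
    S <- vapply(static, function(s) make_species_spectrum(bands[[s]], wavelengths),
                numeric(n_wl))
    A <- S %*% pop[static, , drop = FALSE]
    centers <- scheme$lambda_final +
      (scheme$lambda_initial - scheme$lambda_final) *
      exp(-pmax(delays, 0) / scheme$tau2)
    vis_pop <- pop["e_vis", ] + pop["e_sol", ]
    vb <- bands$e_vis
    for (j in seq_len(n_t)) {
      if (vis_pop[j] == 0) next
      bj <- spectral_band(centers[j], vb$fwhm, vb$amplitude, vb$shape)
      A[, j] <- A[, j] + vis_pop[j] * make_species_spectrum(bj, wavelengths)
    }
  }
  A <- A * dose / 25.3

  uniform <- n_t > 1 && {
    dt <- diff(delays); all(abs(dt - dt[1]) < 1e-8 * abs(dt[1]))
  }
  if (!is.null(irf) && uniform && irf$fwhm >= diff(delays)[1]) {
    for (i in seq_len(n_wl)) A[i, ] <- irf_convolve(A[i, ], irf, delays)
  }

  add_noise <- function() {
    if (noise_sd > 0) A + matrix(stats::rnorm(n_wl * n_t, 0, noise_sd), n_wl, n_t)
    else A
  }
  A <- if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())

  mask <- rep(FALSE, n_wl)
  if (!is.null(mask_window))
    mask <- wavelengths >= mask_window[1] & wavelengths <= mask_window[2]
  ta_matrix(wavelengths, delays, A, mask,
            concentration = scheme$concentration, dose = dose,
            seed = seed, mode = mode)
}

#' Canonical simulated datasets
#'
#' `simulate_default_matrix()` produces the standard picosecond- or
#' microsecond-window matrix at a given concentration with generator defaults.
#' `simulate_deconvolution_matrix()` produces the canonical three-species
#' deconvolution dataset: bilinear mode, log-spaced delays from 300 ps (when
#' electron solvation is complete) to 300 ns, where the excited anion, ground
#' anion and solvated electron are the only species with appreciable
#' population.
#'
#' @param concentration Solute concentration, mol/L.
#' @param mode `"ps"` or `"us"` delay window.
#' @param seed Integer noise seed.
#' @param render `"bilinear"` or `"shifting"`.
#' @param noise_sd Noise SD, OD.
#' @return A [ta_matrix()].
#' @export
simulate_default_matrix <- function(concentration = 0, mode = c("ps", "us"),
                                    seed = NULL,
                                    render = c("bilinear", "shifting"),
                                    noise_sd = 5e-4) {
  mode <- match.arg(mode); render <- match.arg(render)
  simulate_ta_matrix(kinetic_scheme(concentration = concentration),
                     delays = default_delays(mode), mode = render,
                     seed = seed, noise_sd = noise_sd)
}

#' @rdname simulate_default_matrix
#' @param n_delays Number of log-spaced delay points.
#' @export
simulate_deconvolution_matrix <- function(concentration = 0.3, seed = NULL,
                                          noise_sd = 5e-4, n_delays = 150) {
  delays <- 10^seq(log10(300), log10(3e5), length.out = n_delays)
  simulate_ta_matrix(kinetic_scheme(concentration = concentration),
                     delays = delays, mode = "bilinear", seed = seed,
                     noise_sd = noise_sd)
}

#' Band-integrated kinetics
#'
#' Trapezoidal integral of the absorbance over a wavelength window (unmasked
#' rows only), per delay.
#'
#' @param mat A [ta_matrix()].
#' @param window Length-2 wavelength interval, nm.
#' @return Numeric vector over delays, OD nm.
#' @export
band_integrate <- function(mat, window) {
  stopifnot(inherits(mat, "ta_matrix"))
  sel <- which(!mat$mask & mat$wavelengths >= window[1] &
                 mat$wavelengths <= window[2])
  if (length(sel) < 2)
    stop("fewer than 2 unmasked wavelengths in window", call. = FALSE)
  apply(mat$absorbance[sel, , drop = FALSE], 2,
        function(y) pracma::trapz(mat$wavelengths[sel], y))
}

#' Kinetic trace at a wavelength
#'
#' Absorbance versus delay at the requested wavelength, averaged over the
#' unmasked grid points within `bandwidth` nm of it (detector-pixel
#' averaging); `bandwidth = 0` picks the single nearest unmasked row.
#'
#' @param mat A [ta_matrix()].
#' @param wavelength Target wavelength, nm.
#' @param bandwidth Averaging half-width, nm.
#' @return Numeric vector over delays, OD.
#' @export
get_trace <- function(mat, wavelength, bandwidth = 0) {
  stopifnot(inherits(mat, "ta_matrix"))
  ok <- which(!mat$mask)
  if (bandwidth > 0) {
    sel <- ok[abs(mat$wavelengths[ok] - wavelength) <= bandwidth]
    if (length(sel) == 0)
      stop("no unmasked wavelengths within bandwidth", call. = FALSE)
  } else {
    sel <- ok[which.min(abs(mat$wavelengths[ok] - wavelength))]
  }
  colMeans(mat$absorbance[sel, , drop = FALSE])
}

#' Initial near-infrared absorbance
#'
#' Operational definition of the "initial absorbance" used by the scavenging
#' analysis: the mean over the unmasked 900-1000 nm rows and the first
#' `n_delays` grid delays later than `t0 + irf_fwhm` (after the pulse has
#' fully passed).
#'
#' @param mat A [ta_matrix()].
#' @param window Wavelength window, nm.
#' @param irf_fwhm Instrument response FWHM, ps.
#' @param t0 Pulse center, ps.
#' @param n_delays Number of early delays averaged.
#' @return Scalar OD.
#' @export
initial_absorbance <- function(mat, window = c(900, 1000), irf_fwhm = 7,
                               t0 = 0, n_delays = 3) {
  stopifnot(inherits(mat, "ta_matrix"))
  rows <- which(!mat$mask & mat$wavelengths >= window[1] &
                  mat$wavelengths <= window[2])
  cols <- which(mat$delays > t0 + irf_fwhm)[seq_len(n_delays)]
  if (length(rows) == 0 || anyNA(cols))
    stop("initial-absorbance window is empty", call. = FALSE)
  mean(mat$absorbance[rows, cols])
}
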