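#' Spectral band definition
#'
#' A single absorption band of a transient species, parameterized by its
#' center wavelength, full width at half maximum and peak amplitude on the
#' optical-density scale.  The `gaussian` shape is symmetric in wavelength;
#' `lognormal` is a Gaussian in log-wavelength (mildly red-skewed), the usual
#' empirical form for solvated-electron bands.
#'
#' @param center Band maximum position in nm; must lie in \[300, 1300\].
#' @param fwhm Full width at half maximum in nm; must be positive.
#' @param amplitude Peak amplitude (extinction scale, dimensionless >= 0).
#' @param shape `"gaussian"` or `"lognormal"`.
#' @return An object of class `spectral_band`.
#' @export
spectral_band <- function(center, fwhm, amplitude = 1,
                          shape = c("gaussian", "lognormal")) {
  shape <- match.arg(shape)
  if (!is.finite(center) || center < 300 || center > 1300)
    stop("`center` must lie within [300, 1300] nm", call. = FALSE)
  if (!is.finite(fwhm) || fwhm <= 0)
    stop("`fwhm` must be positive", call. = FALSE)
  if (!is.finite(amplitude) || amplitude < 0)
    stop("`amplitude` must be >= 0", call. = FALSE)
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape = shape),
            class = "spectral_band")
}

#' @export
print.spectral_band <- function(x, ...) {
  cat(sprintf("<spectral_band> %s, center %.1f nm, fwhm %.1f nm, amp %.4g\n",
              x$shape, x$center, x$fwhm, x$amplitude))
  invisible(x)
}

#' Evaluate a species spectrum on a wavelength grid
#'
#' @param band A [spectral_band()].
#' @param wavelengths Strictly ascending wavelength grid in nm, within
#'   \[300, 1300\].
#' @return Non-negative numeric vector of the same length as `wavelengths`,
#'   attaining its maximum within one grid step of `band$center` whenever the
#'   center lies inside the grid.
#' @export
make_species_spectrum <- function(band, wavelengths) {
  stopifnot(inherits(band, "spectral_band"))
  if (length(wavelengths) == 0)
    stop("empty wavelength grid", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly ascending", call. = FALSE)
  if (min(wavelengths) < 300 || max(wavelengths) > 1300)
    stop("wavelength grid must lie within [300, 1300] nm", call. = FALSE)
  if (band$amplitude == 0) return(numeric(length(wavelengths)))
  if (band$shape == "gaussian") {
    band$amplitude * exp(-4 * log(2) * ((wavelengths - band$center) / band$fwhm)^2)
  } else {
    # Gaussian in log-wavelength; `a` chosen so the half-maximum points are
    # separated by `fwhm` on the wavelength axis (asinh identity).
    a <- asinh(band$fwhm / (2 * band$center)) / sqrt(log(2))
    band$amplitude * exp(-(log(wavelengths / band$center) / a)^2)
  }
}
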