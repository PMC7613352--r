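## Spectrum container: a wavelength grid plus per-wavelength values and a units
## tag. This is the universal carrier for irradiance E, at-surface irradiance
## Ebar, radiance L, Lbar, transmittance t, reflectance rho and fluorescence F.

.spectrum_units <- c("radiance", "irradiance", "transmittance", "reflectance")

#' Create a spectrum
#'
#' A spectrum is a strictly increasing wavelength grid (nm) with one value per
#' wavelength and a units tag. Radiance is in mW m-2 sr-1 nm-1, irradiance in
#' mW m-2 nm-1; transmittance and reflectance are dimensionless and must lie
#' in [0, 1] (up to a 1e-9 tolerance).
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param value Numeric vector of the same length; all values finite.
#' @param units One of `"radiance"`, `"irradiance"`, `"transmittance"`,
#'   `"reflectance"`.
#' @return An object of class `"spectrum"`.
#' @export
#' @examples
#' s <- spectrum(make_grid(759, 760, 0.5), c(1, 2, 3), "radiance")
#' s$value
spectrum <- function(wavelength, value, units = "radiance") {
  units <- match.arg(units, .spectrum_units)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    stop("wavelength and value must have the same length")
  if (length(wavelength) < 1L) stop("empty spectrum")
  if (anyNA(wavelength) || anyNA(value) || any(!is.finite(value)))
    stop("spectrum values must be finite")
  dw <- diff(wavelength)
  if (length(dw) && any(dw <= 0)) {
    bad <- which(dw <= 0)[1L] + 1L
    stop(sprintf("wavelengths must be strictly increasing (violated at row %d)", bad))
  }
  if (units %in% c("transmittance", "reflectance") &&
      (any(value < -1e-9) || any(value > 1 + 1e-9)))
    stop(sprintf("%s values must lie in [0, 1]", units))
  structure(list(wavelength = wavelength, value = value, units = units),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s, %d points, %.4f-%.4f nm\n",
              x$units, length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Uniform wavelength grid
#'
#' @param start,stop Grid limits in nm, `start < stop`.
#' @param step Grid spacing in nm, positive.
#' @return Numeric vector covering `[start, stop]` with uniform spacing.
#' @export
#' @examples
#' make_grid(759, 760, 0.5)
make_grid <- function(start, stop, step) {
  if (!is.finite(start) || !is.finite(stop) || !is.finite(step))
    stop("grid limits and step must be finite")
  if (step <= 0) stop("step must be positive")
  if (start >= stop) stop("start must be smaller than stop")
  n <- round((stop - start) / step)
  grid <- start + step * seq(0L, n)
  # guarantee coverage of [start, stop] under floating-point rounding
  if (grid[length(grid)] < stop - 1e-9 * step) grid <- c(grid, stop)
  grid
}

# check that two spectra share a wavelength grid
check_common_grid <- function(a, b) {
  if (length(a$wavelength) != length(b$wavelength) ||
      max(abs(a$wavelength - b$wavelength)) > 1e-9)
    stop("spectra are not on a common wavelength grid")
  invisible(TRUE)
}

units_of_product <- function(ua, ub) {
  # multiplying by a transmittance/reflectance keeps the other operand's units
  if (ua == "transmittance") return(ub)
  if (ub == "transmittance") return(ua)
  if (ua == ub) return(ua)
  ua
}

#' @export
Ops.spectrum <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "*", "/"))
    stop(sprintf("operation '%s' not defined for spectra", .Generic))
  if (is_spectrum(e1) && is_spectrum(e2)) {
    check_common_grid(e1, e2)
    v <- get(.Generic)(e1$value, e2$value)
    un <- if (.Generic == "*") units_of_product(e1$units, e2$units) else e1$units
    wl <- e1$wavelength
  } else if (is_spectrum(e1)) {
    v <- get(.Generic)(e1$value, e2)
    un <- e1$units
    wl <- e1$wavelength
  } else {
    v <- get(.Generic)(e1, e2$value)
    un <- e2$units
    wl <- e2$wavelength
  }
  structure(list(wavelength = wl, value = v, units = un), class = "spectrum")
}

#' Evaluate a spectrum at arbitrary wavelengths by linear interpolation
#'
#' @param x A `spectrum`.
#' @param wavelength Wavelengths (nm) inside the support of `x`.
#' @return Numeric vector of interpolated values.
#' @export
spectrum_at <- function(x, wavelength) {
  if (any(wavelength < x$wavelength[1L] - 1e-9) ||
      any(wavelength > x$wavelength[length(x$wavelength)] + 1e-9))
    stop("requested wavelength outside spectrum support")
  stats::approx(x$wavelength, x$value, xout = wavelength, rule = 2)$y
}

#' Restrict a spectrum to a wavelength window
#'
#' @param x A `spectrum`.
#' @param window Length-2 numeric, window limits in nm (inclusive).
#' @return A `spectrum` on the sub-grid.
#' @export
spectrum_window <- function(x, window) {
  keep <- x$wavelength >= window[1L] - 1e-9 & x$wavelength <= window[2L] + 1e-9
  if (!any(keep)) stop("window contains no grid points")
  spectrum(x$wavelength[keep], x$value[keep], x$units)
}
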