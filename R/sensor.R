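## Instrument spectral response: Gaussian ISRF with FWHM = spectral resolution
## (SR), channels spaced by the spectral sampling interval (SSI). The <.>
## operator (convolve + sample at channel centres) lives here, together with
## the convolution-inequality diagnostic that motivates the whole toolkit.

#' Sensor configuration
#'
#' Defines the channelisation operator: a Gaussian instrument spectral
#' response function (ISRF) of full width at half maximum `sr_fwhm` (the
#' spectral resolution, SR), sampled at channel centres spaced by `ssi` (the
#' spectral sampling interval). Channel centres are anchored so that one
#' centre falls exactly on `anchor` (default 760.6 nm, the bottom of the O2-A
#' absorption band) with the remaining centres at integer multiples of `ssi`
#' from it, covering `span`.
#'
#' @param sr_fwhm Spectral resolution (Gaussian FWHM) in nm, positive.
#' @param ssi Spectral sampling interval in nm, positive.
#' @param span Length-2 numeric, wavelength range the channel set must cover.
#' @param anchor Wavelength (nm) on which one channel centre is anchored.
#' @param channel_centers Optional explicit channel centres (overrides
#'   `span`/`anchor`), strictly increasing.
#' @return An object of class `"sensor_config"`.
#' @export
#' @examples
#' cfg <- sensor_config(sr_fwhm = 0.4, ssi = 0.2, span = c(758, 769))
#' range(cfg$channel_centers)
sensor_config <- function(sr_fwhm, ssi, span = c(756.1, 770.6),
                          anchor = 760.6, channel_centers = NULL) {
  if (sr_fwhm <= 0) stop("sr_fwhm must be positive")
  if (ssi <= 0) stop("ssi must be positive")
  if (sr_fwhm < ssi)
    warning("sr_fwhm < ssi: channels undersample the spectral resolution")
  if (is.null(channel_centers)) {
    k_lo <- ceiling((span[1L] - anchor) / ssi - 1e-9)
    k_hi <- floor((span[2L] - anchor) / ssi + 1e-9)
    if (k_hi < k_lo) stop("span contains no channel centres")
    channel_centers <- anchor + ssi * seq(k_lo, k_hi)
  }
  if (any(diff(channel_centers) <= 0))
    stop("channel centres must be strictly increasing")
  structure(list(sr_fwhm = sr_fwhm, ssi = ssi,
                 kernel_shape = "gaussian",
                 channel_centers = channel_centers),
            class = "sensor_config")
}

#' @export
print.sensor_config <- function(x, ...) {
  cat(sprintf("<sensor_config> SR %.3g nm (FWHM), SSI %.3g nm, %d channels %.4f-%.4f nm\n",
              x$sr_fwhm, x$ssi, length(x$channel_centers),
              min(x$channel_centers), max(x$channel_centers)))
  invisible(x)
}

# half-extent of the truncated Gaussian kernel (3 FWHM keeps the truncated
# mass below 1e-12 of the total; the kernel is renormalised anyway)
kernel_half_extent <- function(sr_fwhm) 3 * sr_fwhm

#' Convolve a native-resolution spectrum with the ISRF and sample channels
#'
#' Each channel value is the normalised-kernel-weighted mean of the native
#' spectrum around the channel centre, using trapezoidal quadrature weights on
#' the native grid: a constant spectrum maps to the same constant for any
#' sensor. The Gaussian kernel is truncated at +/- 3 FWHM and renormalised.
#' If the kernel is narrower than the native sampling (the SR -> 0 limit) the
#' nearest native sample is returned.
#'
#' @param x A `spectrum` on a native grid at least 5x finer than `cfg$sr_fwhm`.
#' @param cfg A [sensor_config()].
#' @return A `spectrum` on the channel centres (same units as `x`).
#' @export
convolve_and_sample <- function(x, cfg) {
  stopifnot(is_spectrum(x), inherits(cfg, "sensor_config"))
  wl <- x$wavelength
  n <- length(wl)
  h <- kernel_half_extent(cfg$sr_fwhm)
  ctr <- cfg$channel_centers
  if (ctr[1L] - h < wl[1L] - 1e-9 || ctr[length(ctr)] + h > wl[n] + 1e-9)
    stop("channel span (including kernel extent) exceeds the native support")
  step <- max(diff(wl))
  sigma <- cfg$sr_fwhm / (2 * sqrt(2 * log(2)))
  nearest_only <- (2 * h) < step          # delta-like ISRF limit
  if (!nearest_only && step > cfg$sr_fwhm / 5)
    stop("native sampling must be at least 5x finer than sr_fwhm")
  # trapezoidal quadrature weights on the (possibly non-uniform) native grid
  dw <- diff(wl)
  trap <- c(dw[1L] / 2, (dw[-1L] + dw[-length(dw)]) / 2, dw[length(dw)] / 2)
  vals <- vapply(ctr, function(cc) {
    if (nearest_only) return(x$value[which.min(abs(wl - cc))])
    i1 <- findInterval(cc - h, wl) ; i1 <- max(i1, 1L)
    i2 <- findInterval(cc + h, wl) + 1L ; i2 <- min(i2, n)
    w <- exp(-((wl[i1:i2] - cc)^2) / (2 * sigma^2)) * trap[i1:i2]
    sum(w * x$value[i1:i2]) / sum(w)
  }, numeric(1L))
  if (x$units %in% c("transmittance", "reflectance"))
    vals <- pmin(pmax(vals, 0), 1)        # guard rounding at the [0,1] edges
  spectrum(ctr, vals, x$units)
}

#' Convolution-inequality diagnostic (relative difference per channel)
#'
#' Quantifies the error committed when a channelised radiance is divided by a
#' separately channelised transmittance: for a native surface radiance Lbar
#' and native path transmittance t, returns per channel
#' `RD = 100 * (<Lbar t>/<t> - <Lbar>) / <Lbar>` (in per cent). It is zero
#' for constant transmittance and grows with the absorption depth and with
#' the within-channel co-structure of Lbar and t.
#'
#' @param L A `spectrum`: the native (surface-level) radiance.
#' @param t A `spectrum`: the native path transmittance, strictly positive.
#' @param cfg A [sensor_config()].
#' @return A `spectrum` of relative differences in per cent on the channels
#'   (units tag `"radiance"` is replaced by a dimensionless interpretation).
#' @export
convolution_inequality_rd <- function(L, t, cfg) {
  stopifnot(is_spectrum(L), is_spectrum(t))
  check_common_grid(L, t)
  if (any(t$value <= 0)) stop("transmittance must be strictly positive")
  Lt <- convolve_and_sample(L * t, cfg)
  tc <- convolve_and_sample(t, cfg)
  Lc <- convolve_and_sample(L, cfg)
  if (any(tc$value <= 0)) stop("channelised transmittance must be positive")
  rd <- 100 * (Lt$value / tc$value - Lc$value) / Lc$value
  structure(list(wavelength = Lc$wavelength, value = rd, units = "radiance"),
            class = "spectrum")
}
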