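## Forward model: synthetic reference reflectance, SIF emission and solar
## irradiance, and propagation from the canopy to the sensor. The scene
## generator is fully deterministic given its configuration.

#' Surface state (reflectance + fluorescence)
#'
#' @param rho Reflectance `spectrum` (values in [0, 1]).
#' @param F_sif Fluorescence `spectrum` (radiance units, non-negative).
#' @return An object of class `"surface_state"`.
#' @export
surface_state <- function(rho, F_sif) {
  stopifnot(is_spectrum(rho), is_spectrum(F_sif))
  check_common_grid(rho, F_sif)
  if (any(F_sif$value < 0)) stop("fluorescence must be non-negative")
  structure(list(rho = rho, F = F_sif), class = "surface_state")
}

#' Synthetic vegetation reflectance
#'
#' A smooth vegetation-like curve: a logistic red edge centred near 715 nm
#' rising from a low red floor to a near-infrared plateau at `level`. The
#' curve is effectively constant at the O2-band scale (variation below 1e-3
#' per 0.1 nm), which is what makes low-order polynomial reflectance models
#' adequate over the retrieval window.
#'
#' @param grid Wavelength grid (nm).
#' @param level NIR plateau reflectance, in (0, 1).
#' @param red_edge If `FALSE`, return a flat spectrum at `level`.
#' @return A reflectance `spectrum`.
#' @export
synth_reflectance <- function(grid, level = 0.5, red_edge = TRUE) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (!red_edge) return(spectrum(grid, rep(level, length(grid)), "reflectance"))
  floor_refl <- 0.05 * level
  v <- floor_refl + (level - floor_refl) / (1 + exp(-(grid - 715) / 8))
  spectrum(grid, v, "reflectance")
}

#' Synthetic two-peak SIF emission spectrum
#'
#' Sum of two Gaussians centred at 687 nm (red peak, sd 10 nm) and 741 nm
#' (far-red peak, sd 25 nm). With the default peaks the spectrum is rescaled
#' so that F(760.6 nm) = `norm_760` (0.97 mW m-2 sr-1 nm-1, the reference SIF
#' level at the bottom of the O2-A band).
#'
#' @param grid Wavelength grid (nm).
#' @param peak_red,peak_farred Unnormalised Gaussian amplitudes
#'   (mW m-2 sr-1 nm-1), non-negative.
#' @param width_red,width_farred Gaussian standard deviations (nm).
#' @param norm_760 Target value at 760.6 nm, or `NULL` to skip rescaling.
#' @return A radiance `spectrum`.
#' @export
#' @examples
#' F <- synth_sif(make_grid(650, 800, 0.5))
#' spectrum_at(F, 760.6)  # 0.97
synth_sif <- function(grid, peak_red = 1.5, peak_farred = 1.2,
                      width_red = 10, width_farred = 25, norm_760 = 0.97) {
  if (peak_red < 0 || peak_farred < 0) stop("peaks must be non-negative")
  shape <- function(wl) {
    peak_red * exp(-((wl - 687)^2) / (2 * width_red^2)) +
      peak_farred * exp(-((wl - 741)^2) / (2 * width_farred^2))
  }
  v <- shape(grid)
  if (!is.null(norm_760)) {
    ref <- shape(760.6)
    if (ref > 0) v <- v * (norm_760 / ref)
  }
  spectrum(grid, v, "radiance")
}

#' Smooth solar irradiance baseline
#'
#' A blackbody-like (5800 K) curve scaled to ~1420 mW m-2 nm-1 at 760 nm,
#' strictly positive and spectrally smooth. Solar Fraunhofer lines are not
#' modelled: the retrieval windows exploit the telluric O2 features only,
#' which the scene generator imprints separately.
#'
#' @param grid Wavelength grid (nm).
#' @param level Irradiance at 760 nm in mW m-2 nm-1.
#' @return An irradiance `spectrum`.
#' @export
synth_solar_irradiance <- function(grid, level = 1420) {
  planck <- function(wl_nm) {
    wl <- wl_nm * 1e-9
    1 / (wl^5 * (exp(0.0143877688 / (wl * 5800)) - 1))
  }
  v <- level * planck(grid) / planck(760)
  spectrum(grid, v, "irradiance")
}

#' At-surface solar irradiance
#'
#' `Ebar = E * t_down` pointwise: the irradiance measured at sensor level
#' propagated down to the canopy through the short-path transmittance.
#'
#' @param E Irradiance `spectrum` at sensor level.
#' @param t_down Downward transmittance `spectrum` on the same grid.
#' @return An irradiance `spectrum`.
#' @export
surface_irradiance <- function(E, t_down) {
  stopifnot(is_spectrum(E), is_spectrum(t_down))
  check_common_grid(E, t_down)
  spectrum(E$wavelength, E$value * t_down$value, "irradiance")
}

#' Top-of-canopy radiance
#'
#' `Lbar = rho * Ebar / pi + F`: reflected solar irradiance (Lambertian
#' surface) plus the additive SIF emission.
#'
#' @param surface A [surface_state()].
#' @param E_bar At-surface irradiance `spectrum` on the same grid.
#' @return A radiance `spectrum`.
#' @export
toc_radiance <- function(surface, E_bar) {
  stopifnot(inherits(surface, "surface_state"), is_spectrum(E_bar))
  check_common_grid(surface$rho, E_bar)
  spectrum(E_bar$wavelength,
           surface$rho$value * E_bar$value / pi + surface$F$value,
           "radiance")
}

#' At-sensor radiance
#'
#' `L = Lbar * t_up`: the top-of-canopy radiance attenuated along the
#' canopy-to-sensor path.
#'
#' @param L_bar Top-of-canopy radiance `spectrum`.
#' @param t_up Upward transmittance `spectrum` on the same grid, in (0, 1].
#' @return A radiance `spectrum`.
#' @export
at_sensor_radiance <- function(L_bar, t_up) {
  stopifnot(is_spectrum(L_bar), is_spectrum(t_up))
  check_common_grid(L_bar, t_up)
  if (any(t_up$value <= 0)) stop("t_up must be strictly positive")
  spectrum(L_bar$wavelength, L_bar$value * t_up$value, "radiance")
}

#' Apparent reflectance
#'
#' `rho_app = pi * L / E`: the ratio of up-welling radiance to down-welling
#' irradiance, both taken at the same level, without removing fluorescence or
#' path transmittance. Fluorescence in-filling shows up as in-band peaks at
#' canopy level; with increasing sensor height the peaks flatten and can
#' invert into depressions.
#'
#' @param L Radiance `spectrum`.
#' @param E Irradiance `spectrum` on the same grid, strictly positive.
#' @return A `spectrum` (values may exceed 1 inside absorption features, so
#'   the units tag is `"radiance"`-free dimensionless stored as reflectance
#'   with clamping disabled via a plain list).
#' @export
apparent_reflectance <- function(L, E) {
  stopifnot(is_spectrum(L), is_spectrum(E))
  check_common_grid(L, E)
  if (any(E$value <= 0)) stop("irradiance must be strictly positive")
  structure(list(wavelength = L$wavelength, value = pi * L$value / E$value,
                 units = "reflectance"),
            class = "spectrum")
}

## ---- scene -----------------------------------------------------------------

#' Build and simulate a proximal-sensing scene
#'
#' Generates the full synthetic measurement configuration at native spectral
#' resolution: a smooth top-of-atmosphere-like solar baseline carrying the
#' total-column O2 imprint down to the sensor, the short-path downward and
#' upward transmittances (O2 and aerosol), the at-surface irradiance, the
#' top-of-canopy radiance and the at-sensor radiance. Everything is
#' deterministic given the configuration.
#'
#' @param band `"O2A"` or `"O2B"`.
#' @param height_m Sensor height above the canopy in m.
#' @param sza,vza Solar and view zenith angles in degrees.
#' @param temperature Air temperature in K.
#' @param pressure Surface pressure in hPa.
#' @param rho_level NIR reflectance plateau.
#' @param aot550 Aerosol optical thickness at 550 nm (total column).
#' @param sif_norm SIF level at 760.6 nm (`NULL` to skip normalisation).
#' @param lines Optional calibrated line list (defaults to the band's).
#' @param include_column Imprint the total-column O2 absorption on the
#'   at-sensor irradiance (default `TRUE`).
#' @param grid_step Native grid step in nm.
#' @return An object of class `"scene"`: a list with the native `spectrum`
#'   fields `E0` (smooth baseline), `E` (at-sensor irradiance), `E_bar`,
#'   `L_bar`, `L`, the transmittances `t_up_O2`, `t_down_O2`, `t_up_aer`,
#'   `t_up_total`, `t_col`, the `surface`, `geom`, `cond` and band metadata.
#' @export
#' @examples
#' sc <- make_scene(height_m = 10)
#' max(sc$L$value) < max(sc$L_bar$value)
make_scene <- function(band = "O2A", height_m = 10, sza = 30, vza = 0,
                       temperature = 288.15, pressure = 1013.25,
                       rho_level = 0.5, aot550 = 0.1, sif_norm = 0.97,
                       lines = NULL, include_column = TRUE,
                       grid_step = 0.005) {
  bd <- band_defaults(band)
  grid <- native_grid(band, grid_step)
  if (is.null(lines)) lines <- default_line_list(band)
  geom <- path_geometry(height_m = height_m, sza = sza, vza = vza)
  cond <- gas_conditions(temperature, pressure, Z_km = height_m / 1000)

  rho <- synth_reflectance(grid, level = rho_level)
  F_sif <- synth_sif(grid, norm_760 = sif_norm)
  surface <- surface_state(rho, F_sif)

  E0 <- synth_solar_irradiance(grid)
  t_col <- if (include_column) {
    line_by_line_transmittance(grid, lines, column_conditions(column_path_km(band)),
                               geom, "down")
  } else spectrum(grid, rep(1, length(grid)), "transmittance")
  E <- spectrum(grid, E0$value * t_col$value, "irradiance")

  if (height_m > 0) {
    t_up_O2 <- line_by_line_transmittance(grid, lines, cond, geom, "up")
    t_down_O2 <- line_by_line_transmittance(grid, lines, cond, geom, "down")
  } else {
    ones <- rep(1, length(grid))
    t_up_O2 <- t_down_O2 <- spectrum(grid, ones, "transmittance")
  }
  t_up_aer <- aerosol_transmittance(grid, aot550, geom, "up")
  t_down_aer <- aerosol_transmittance(grid, aot550, geom, "down")
  t_up_total <- total_transmittance(t_up_O2, t_up_aer)
  t_down_total <- total_transmittance(t_down_O2, t_down_aer)

  E_bar <- surface_irradiance(E, t_down_total)
  L_bar <- toc_radiance(surface, E_bar)
  L <- at_sensor_radiance(L_bar, t_up_total)

  structure(list(band = band, grid = grid, surface = surface, geom = geom,
                 cond = cond, lines = lines,
                 E0 = E0, t_col = t_col, E = E,
                 t_up_O2 = t_up_O2, t_down_O2 = t_down_O2,
                 t_up_aer = t_up_aer, t_down_aer = t_down_aer,
                 t_up_total = t_up_total, t_down_total = t_down_total,
                 E_bar = E_bar, L_bar = L_bar, L = L),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %s band, height %.1f m, SZA %.1f, VZA %.1f, T %.2f K, p %.2f hPa\n",
              x$band, x$geom$height_m, x$geom$sza, x$geom$vza,
              x$cond$T_K, x$cond$p_atm * .proxsif_constants$atm_hPa))
  invisible(x)
}

#' Channelise all scene signals with a sensor configuration
#'
#' @param scene A [make_scene()] result.
#' @param cfg A [sensor_config()].
#' @return A named list of channelised `spectrum` objects (`E`, `E_bar`,
#'   `L_bar`, `L`, `t_up_O2`, `t_down_O2`, `t_up_total`, `t_down_total`,
#'   `F`, `rho`).
#' @export
channelize_scene <- function(scene, cfg) {
  stopifnot(inherits(scene, "scene"), inherits(cfg, "sensor_config"))
  lapply(list(E = scene$E, E_bar = scene$E_bar, L_bar = scene$L_bar,
              L = scene$L,
              t_up_O2 = scene$t_up_O2, t_down_O2 = scene$t_down_O2,
              t_up_total = scene$t_up_total, t_down_total = scene$t_down_total,
              F = scene$surface$F, rho = scene$surface$rho),
         convolve_and_sample, cfg = cfg)
}
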