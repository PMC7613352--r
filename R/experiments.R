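## Scripted reproductions of the simulation studies: retrieval-error sweeps
## over sensor heights and spectral configurations, the seasonal T/p analysis
## with a synthetic meteorological series, and the null-target validation.

#' Sweep specification
#'
#' @param heights_m Sensor heights above the canopy in m.
#' @param sensor_configs List of `c(ssi, sr)` pairs in nm.
#' @param setups Subset of the measurement set-ups 1-4.
#' @param methods Retrieval methods: any of `"fld"`, `"3fld"`, `"ifld"`,
#'   `"sfm"`, `"sfm-conv"`.
#' @return An object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(heights_m = c(3, 5, 10, 15, 20),
                       sensor_configs = list(c(0.1, 0.1), c(0.2, 0.4),
                                             c(0.5, 1.0), c(1.0, 2.0)),
                       setups = 1:4, methods = "3fld") {
  if (any(heights_m < 0)) stop("heights must be non-negative")
  for (sc in sensor_configs)
    if (sc[2L] < sc[1L])
      warning(sprintf("SR %.3g nm < SSI %.3g nm: undersampled configuration",
                      sc[2L], sc[1L]))
  if (!all(setups %in% 1:4)) stop("setups must be within 1-4")
  methods <- match.arg(methods, c("fld", "3fld", "ifld", "sfm", "sfm-conv"),
                       several.ok = TRUE)
  structure(list(heights_m = heights_m, sensor_configs = sensor_configs,
                 setups = setups, methods = methods),
            class = "sweep_spec")
}

# FLD-family estimate for one measurement set-up from channelised scene signals
fld_for_setup <- function(ch, setup, bands, alpha, strict_paper = FALSE) {
  switch(as.character(setup),
    "1" = fld_o2(ch$E_bar, ch$L, ch$t_up_O2, ch$t_down_O2, bands, alpha,
                 E_is_toc = TRUE, strict_paper = strict_paper),
    "2" = fld_family(ch$E_bar, ch$L, bands, alpha),
    "3" = fld_o2(ch$E, ch$L, ch$t_up_O2, ch$t_down_O2, bands, alpha,
                 E_is_toc = FALSE, strict_paper = strict_paper),
    "4" = fld_family(ch$E, ch$L, bands, alpha))
}

# sensor-level SFM estimate for one set-up (first-order O2 compensation)
sfm_for_setup <- function(ch, setup, cfg, fg, F_true) {
  ones <- spectrum(ch$L$wavelength, rep(1, length(ch$L$wavelength)),
                   "transmittance")
  switch(as.character(setup),
    "1" = sfm_fit_o2(ch$E_bar, ch$L, ones, ch$t_up_O2, cfg, fg,
                     E_is_toc = TRUE, F_true = F_true),
    "2" = sfm_fit_o2(ch$E_bar, ch$L, ones, ones, cfg, fg,
                     E_is_toc = TRUE, F_true = F_true),
    "3" = sfm_fit_o2(ch$E, ch$L, ch$t_down_O2, ch$t_up_O2, cfg, fg,
                     E_is_toc = FALSE, F_true = F_true),
    "4" = sfm_fit_o2(ch$E, ch$L, ones, ones, cfg, fg,
                     E_is_toc = FALSE, F_true = F_true))
}

#' Retrieval-error sweep over heights, sensor configurations and set-ups
#'
#' For every cell (height x sensor configuration x set-up x method) the scene
#' is simulated, channelised and retrieved, and the relative error against
#' the channelised reference SIF is recorded at 760.6 nm (and as the maximum
#' over 759-768 nm for spectrum-valued methods). A top-of-canopy baseline
#' retrieval per configuration and method is included as `setup = 0` rows.
#' Failures are recorded per cell (`NA` estimate), not raised.
#'
#' @param spec A [sweep_spec()].
#' @param band `"O2A"` or `"O2B"`.
#' @param sfm_cfg An [sfm_config()] for the SFM-family methods.
#' @param scene_args Extra arguments passed to [make_scene()].
#' @return A `data.frame` with one row per cell: `height_m`, `ssi`, `sr`,
#'   `setup`, `method`, `F_est`, `F_true`, `rel_err_pct`, `max_err_pct`.
#' @export
run_sweep <- function(spec = sweep_spec(), band = "O2A",
                      sfm_cfg = sfm_config(), scene_args = list()) {
  stopifnot(inherits(spec, "sweep_spec"))
  bands3 <- fld_band_set()
  bands1 <- fld_band_set(lambda_out = 758.0)
  alpha1 <- alpha_coefficients()
  rows <- list()
  err_window <- c(759, 768)
  for (h in spec$heights_m) {
    sc <- do.call(make_scene, c(list(band = band, height_m = h), scene_args))
    mask_path <- spectrum(sc$grid,
                          pmin(sc$t_down_O2$value * sc$t_up_O2$value, 1),
                          "transmittance")
    for (cfgv in spec$sensor_configs) {
      sensor <- sensor_config(sr_fwhm = cfgv[2L], ssi = cfgv[1L],
                              anchor = band_defaults(band)$anchor,
                              span = band_defaults(band)$channel_span)
      ch <- channelize_scene(sc, sensor)
      F_true_760 <- spectrum_at(ch$F, band_defaults(band)$anchor)
      rho_app <- apparent_reflectance(ch$L, ch$E)
      fg <- tryCatch(sfm_first_guess(ch$F, rho_app, sfm_cfg, mask_path, sensor,
                                     col_t = sc$t_col),
                     error = function(e) NULL)
      # channel-level clean/absorbed indicator for the iFLD smooth fit
      ch_ok <- spectrum(ch$L$wavelength,
                        as.numeric(convolve_and_sample(mask_path, sensor)$value >= 0.995 &
                                     convolve_and_sample(sc$t_col, sensor)$value >= 0.95),
                        "transmittance")
      atm_fit <- NULL
      for (m in spec$methods) {
        setups_m <- if (m == "sfm-conv") intersect(spec$setups, 1L) else spec$setups
        for (s in c(0L, setups_m)) {    # 0 = TOC baseline
          est <- tryCatch({
            if (m %in% c("fld", "3fld", "ifld")) {
              bnd <- if (m == "fld") bands1 else bands3
              alp <- if (m == "ifld")
                ifld_alpha(rho_app, bnd, mask_t = ch_ok, F_ref = ch$F)
              else alpha1
              if (s == 0L) {
                F_est <- fld_family(ch$E_bar, ch$L_bar, bnd, alp)
              } else {
                F_est <- fld_for_setup(ch, s, bnd, alp)
              }
              list(F_est = F_est, max_err = NA_real_)
            } else if (m == "sfm") {
              r <- if (s == 0L)
                sfm_fit(ch$E_bar, ch$L_bar, sfm_cfg, fg, F_true = ch$F)
              else sfm_for_setup(ch, s, sfm_cfg, fg, ch$F)
              list(F_est = spectrum_at(r$F_est, band_defaults(band)$anchor),
                   max_err = max(abs(r$rel_error_pct[
                     r$F_est$wavelength >= err_window[1L] &
                       r$F_est$wavelength <= err_window[2L]])))
            } else {                     # sfm-conv
              if (s == 0L) {
                r <- sfm_fit(ch$E_bar, ch$L_bar, sfm_cfg, fg, F_true = ch$F)
              } else {
                if (is.null(atm_fit))
                  atm_fit <- fit_atmosphere(ch$E, sensor, sc$lines, sc$geom,
                                            band = band)
                atm <- model_atmosphere(atm_fit, h,
                                        temperature = sc$cond$T_K,
                                        pressure = sc$cond$p_atm *
                                          .proxsif_constants$atm_hPa)
                r <- sfm_fit_convolved(ch$L, atm, sensor, sfm_cfg, fg,
                                       F_true = ch$F)
              }
              list(F_est = spectrum_at(r$F_est, band_defaults(band)$anchor),
                   max_err = max(abs(r$rel_error_pct[
                     r$F_est$wavelength >= err_window[1L] &
                       r$F_est$wavelength <= err_window[2L]])))
            }
          }, error = function(e) list(F_est = NA_real_, max_err = NA_real_))
          rows[[length(rows) + 1L]] <- data.frame(
            height_m = h, ssi = cfgv[1L], sr = cfgv[2L], setup = s, method = m,
            F_est = est$F_est, F_true = F_true_760,
            rel_err_pct = 100 * (est$F_est - F_true_760) / F_true_760,
            max_err_pct = est$max_err)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- seasonal T/p analysis -------------------------------------------------

#' Synthetic annual meteorological series
#'
#' A sinusoidal annual cycle with the temperature minimum near day-of-year 1
#' and the maximum near DOY 180; the surface pressure cycle is either
#' anticorrelated with temperature (winter-high, the default) or held
#' constant. Optional seeded day-to-day Gaussian noise.
#'
#' @param T_mean_K,T_swing_K Mean and peak-to-peak swing of air temperature.
#' @param p_mean_hPa,p_swing_hPa Mean and peak-to-peak swing of surface
#'   pressure.
#' @param n_days Series length (days).
#' @param p_phase `"anticorrelated"` (pressure maximum in winter) or
#'   `"independent"` (constant pressure).
#' @param noise_T_K,noise_p_hPa Standard deviations of daily noise.
#' @param seed Integer seed for the noise (ignored when both noises are 0).
#' @param sensor_height_m Height of the sensor above the canopy, carried as
#'   metadata for the seasonal transmittance computation.
#' @return A `data.frame` of class `"met_series"` with columns `doy`, `T_K`,
#'   `p_hPa`.
#' @export
synth_met_series <- function(T_mean_K = 277.15, T_swing_K = 40,
                             p_mean_hPa = 1000, p_swing_hPa = 50,
                             n_days = 365,
                             p_phase = c("anticorrelated", "independent"),
                             noise_T_K = 0, noise_p_hPa = 0, seed = 0,
                             sensor_height_m = 15) {
  p_phase <- match.arg(p_phase)
  if (T_swing_K < 0 || p_swing_hPa < 0) stop("swings must be non-negative")
  doy <- seq_len(n_days)
  phase <- cos(2 * pi * (doy - 1) / 365)
  T_K <- T_mean_K - T_swing_K / 2 * phase
  p_hPa <- if (p_phase == "anticorrelated")
    p_mean_hPa + p_swing_hPa / 2 * phase
  else rep(p_mean_hPa, n_days)
  if (noise_T_K > 0 || noise_p_hPa > 0) {
    set.seed(seed)
    T_K <- T_K + stats::rnorm(n_days, 0, noise_T_K)
    p_hPa <- p_hPa + stats::rnorm(n_days, 0, noise_p_hPa)
  }
  out <- data.frame(doy = doy, T_K = T_K, p_hPa = p_hPa)
  attr(out, "sensor_height_m") <- sensor_height_m
  class(out) <- c("met_series", "data.frame")
  out
}

# default band-model coefficients: Pierluisi C' fitted against the calibrated
# line-by-line engine at reference conditions over the band's 0.22 nm channels
default_pierluisi <- function(band = "O2A", Z_km = 0.015) {
  key <- paste0("pier_", band, "_", Z_km)
  if (!is.null(.proxsif_cache[[key]])) return(.proxsif_cache[[key]])
  lines <- default_line_list(band)
  grid <- native_grid(band)
  cond <- gas_conditions(288.15, 1013.25, Z_km = Z_km)
  t_nat <- line_by_line_transmittance(grid, lines, cond,
                                      path_geometry(sza = 0, vza = 0), "up")
  t_ref <- convolve_and_sample(t_nat, bandmodel_sensor(band))
  pp <- fit_pierluisi_coefficients(t_ref, cond)
  .proxsif_cache[[key]] <- pp
  pp
}

#' Seasonal O2 transmittance from a meteorological series
#'
#' For each day, evaluates the empirical band model at the day's temperature
#' and pressure (surface pressure mapped to the mid-path height) over the
#' band's 0.22 nm channels, and returns the per-day band-minimum
#' transmittance together with the channel spectra.
#'
#' @param met A [synth_met_series()] (or equivalent) series.
#' @param path_m Vertical optical path between canopy and sensor in m.
#' @param band `"O2A"` or `"O2B"`.
#' @param params Optional [pierluisi_params()]; defaults to coefficients
#'   fitted against the packaged line-by-line engine for this path.
#' @return A list with `doy`, `band_min` (per-day minimum transmittance),
#'   `spectra` (matrix channels x days), `wavelength`, and
#'   `seasonal_change = max(band_min) - min(band_min)`.
#' @export
seasonal_transmittance <- function(met, path_m = 15, band = "O2A",
                                   params = NULL) {
  stopifnot(inherits(met, "met_series"))
  if (is.null(params)) params <- default_pierluisi(band, Z_km = path_m / 1000)
  n <- nrow(met)
  wl <- params$Cprime$wavelength
  spectra <- matrix(NA_real_, length(wl), n)
  band_min <- numeric(n)
  for (i in seq_len(n)) {
    p_mid <- pressure_at_height(met$p_hPa[i], met$T_K[i], path_m / 2)
    cond <- gas_conditions(met$T_K[i], p_mid, Z_km = path_m / 1000)
    t <- pierluisi_transmittance(params, cond)
    spectra[, i] <- t$value
    band_min[i] <- min(t$value)
  }
  list(doy = met$doy, band_min = band_min, spectra = spectra, wavelength = wl,
       seasonal_change = max(band_min) - min(band_min))
}

#' Seasonal at-sensor radiance variation with invariant surface
#'
#' Keeps the surface reflectance and SIF fixed and recomputes the upward
#' short-path O2 transmittance at native resolution for every day of the
#' series; returns the radiance difference `L_sen(DOY) - L_sen(DOY = 1)`.
#' Any apparent seasonal trend in this quantity is entirely atmospheric.
#'
#' @param met A [synth_met_series()] series.
#' @param band `"O2A"` or `"O2B"`.
#' @param path_m Vertical path in m.
#' @param scene_args Extra arguments for the reference [make_scene()].
#' @return A list with `doy`, `max_abs_delta` (per-day maximum |delta L|
#'   over the band), `overall_max` (maximum over the year), and `delta`
#'   (matrix wavelengths x days, native grid).
#' @export
seasonal_radiance_delta <- function(met, band = "O2A", path_m = 15,
                                    scene_args = list()) {
  stopifnot(inherits(met, "met_series"))
  sc <- do.call(make_scene,
                c(list(band = band, height_m = path_m,
                       temperature = met$T_K[1L],
                       pressure = met$p_hPa[1L]),
                  scene_args))
  grid <- sc$grid
  L_bar <- sc$L_bar$value
  geom <- sc$geom
  lines <- sc$lines
  n <- nrow(met)
  t_of_day <- function(i) {
    p_mid <- pressure_at_height(met$p_hPa[i], met$T_K[i], path_m / 2)
    cond <- gas_conditions(met$T_K[i], p_mid, Z_km = path_m / 1000)
    line_by_line_transmittance(grid, lines, cond, geom, "up")$value
  }
  t1 <- t_of_day(1L)
  delta <- matrix(NA_real_, length(grid), n)
  max_abs <- numeric(n)
  for (i in seq_len(n)) {
    d <- L_bar * (t_of_day(i) - t1)
    delta[, i] <- d
    max_abs[i] <- max(abs(d))
  }
  list(doy = met$doy, max_abs_delta = max_abs, overall_max = max(max_abs),
       delta = delta, wavelength = grid)
}

#' Null-target validation: residual band structure in recovered reflectance
#'
#' For a non-fluorescent target, the surface reflectance recovered as
#' `rho = pi (L / t_up_model) / (E t_down_model)` should show no structure
#' inside the absorption band; the returned score is the maximum in-band
#' deviation from a smooth (cubic) fit to the unabsorbed channels, and is
#' near zero exactly when the modelled transmittance matches the true
#' atmospheric state.
#'
#' @param L Channelised at-sensor radiance of the non-fluorescent target.
#' @param E Channelised at-sensor irradiance.
#' @param t_up_model,t_down_model Channelised modelled transmittances.
#' @param mask_t Channelised transmittance identifying absorbed channels
#'   (threshold 0.995).
#' @param window Evaluation window (nm): the smooth fit and the deviation are
#'   both restricted to it, so that surface-reflectance curvature far from
#'   the band does not leak into the score.
#' @return Maximum absolute in-band deviation of the recovered reflectance
#'   from the smooth out-of-band fit.
#' @export
null_target_validation <- function(L, E, t_up_model, t_down_model, mask_t,
                                   window = c(757, 769.5)) {
  stopifnot(is_spectrum(L), is_spectrum(E))
  rho_rec <- pi * (L$value / t_up_model$value) /
    (E$value * t_down_model$value)
  wl <- L$wavelength
  inw <- wl >= window[1L] & wl <= window[2L]
  rho_rec <- rho_rec[inw]; wl <- wl[inw]
  clean <- mask_t$value[inw] >= 0.995
  if (sum(clean) < 5L) stop("too few unabsorbed channels")
  fit <- stats::lm(v ~ poly(w, 3, raw = TRUE),
                   data = data.frame(w = wl[clean], v = rho_rec[clean]))
  smooth <- stats::predict(fit, newdata = data.frame(w = wl))
  if (all(clean)) return(max(abs(rho_rec - smooth)))
  max(abs(rho_rec[!clean] - smooth[!clean]))
}
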