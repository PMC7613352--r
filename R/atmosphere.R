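## O2 (and simple aerosol) transmittance along the canopy-sensor path: a
## synthetic line-by-line engine (deterministic stand-in for a full radiative
## transfer code driven by a molecular line database), the Pierluisi empirical
## band model, pressure/temperature scaling and path geometry.

#' Gas conditions along an absorption path
#'
#' @param temperature Air temperature in K.
#' @param pressure Pressure; hPa by default, atm if `pressure_units = "atm"`.
#' @param M Absorber (O2) concentration in ppmv.
#' @param rho_a Air density in g m-3; computed from temperature and pressure
#'   via the ideal gas law when `NULL`.
#' @param Z_km Path length in km (vertical unless slanted by geometry).
#' @param pressure_units `"hPa"` (default) or `"atm"`.
#' @return An object of class `"gas_conditions"` with fields `T_K`, `p_atm`,
#'   `M_ppmv`, `rho_a`, `Z_km`.
#' @export
#' @examples
#' gas_conditions(288.15, 1013.25, Z_km = 0.015)$rho_a  # ~1225 g m-3
gas_conditions <- function(temperature, pressure, M = .proxsif_constants$M_O2,
                           rho_a = NULL, Z_km = 0, pressure_units = c("hPa", "atm")) {
  pressure_units <- match.arg(pressure_units)
  p_atm <- if (pressure_units == "hPa") pressure / .proxsif_constants$atm_hPa else pressure
  if (temperature <= 0) stop("temperature must be positive (K)")
  if (p_atm <= 0) stop("pressure must be positive")
  if (M < 0) stop("absorber concentration must be non-negative")
  if (Z_km < 0) stop("path length must be non-negative")
  if (is.null(rho_a)) {
    p_Pa <- p_atm * .proxsif_constants$atm_hPa * 100
    rho_a <- p_Pa / (.proxsif_constants$R_dry * temperature) * 1000  # g m-3
  }
  if (rho_a <= 0) stop("air density must be positive")
  structure(list(T_K = temperature, p_atm = p_atm, M_ppmv = M,
                 rho_a = rho_a, Z_km = Z_km),
            class = "gas_conditions")
}

#' Path geometry between canopy and sensor
#'
#' @param height_m Sensor height above the canopy in m (non-negative).
#' @param sza Solar zenith angle in degrees, `0 <= sza < 90`.
#' @param vza View zenith angle in degrees, `0 <= vza < 90`.
#' @return An object of class `"path_geometry"`.
#' @export
path_geometry <- function(height_m = 10, sza = 30, vza = 0) {
  if (height_m < 0) stop("height must be non-negative")
  if (sza < 0 || sza >= 90) stop("sza must be in [0, 90)")
  if (vza < 0 || vza >= 90) stop("vza must be in [0, 90)")
  structure(list(height_m = height_m, sza = sza, vza = vza),
            class = "path_geometry")
}

airmass <- function(angle_deg) 1 / cos(angle_deg * pi / 180)

#' Total absorber amount along a path
#'
#' `U = 0.7732e-4 * M * rho_a * Z` in atm cm, with M in ppmv, rho_a in g m-3
#' and Z in km.
#'
#' @param cond A [gas_conditions()].
#' @return Absorber amount U in atm cm.
#' @export
#' @examples
#' absorber_amount(gas_conditions(288.15, 1013.25, Z_km = 0.015))
absorber_amount <- function(cond) {
  stopifnot(inherits(cond, "gas_conditions"))
  .proxsif_constants$U_coef * cond$M_ppmv * cond$rho_a * cond$Z_km
}

#' Pierluisi empirical O2 band-model parameters
#'
#' Bundles the fixed exponents of the empirical O2 transmittance law
#' `t = exp[-(10^C'(lambda) (p/p0)^n (T0/T)^m U)^a]` together with a
#' per-channel coefficient spectrum `C'` on a moderate-resolution
#' (~0.22 nm) channel grid.
#'
#' @param Cprime A `spectrum` (units `"transmittance"` slot unused; values are
#'   log10 absorption coefficients) on the band-model channel grid.
#' @param flagged Logical vector marking channels where `C'` was clamped
#'   because the reference transmittance was exactly 1.
#' @return An object of class `"pierluisi_params"`.
#' @export
pierluisi_params <- function(Cprime, flagged = rep(FALSE, length(Cprime$wavelength))) {
  k <- .proxsif_constants
  structure(list(a = k$pier_a, m = k$pier_m, n = k$pier_n,
                 T0 = k$pier_T0, p0 = k$pier_p0,
                 Cprime = Cprime, flagged = flagged),
            class = "pierluisi_params")
}

#' O2 transmittance from the Pierluisi band model
#'
#' Evaluates `t(lambda) = exp[-(10^C'(lambda) (p/p0)^n (T0/T)^m U)^a]` on the
#' band-model channel grid (valid at ~0.22 nm resolution).
#'
#' @param params A [pierluisi_params()].
#' @param cond A [gas_conditions()]; `U` is computed via [absorber_amount()].
#' @param grid Optional wavelengths (nm); must be a subset of the `C'` grid
#'   support (values are interpolated linearly in `C'`).
#' @return A transmittance `spectrum`.
#' @export
pierluisi_transmittance <- function(params, cond, grid = NULL) {
  stopifnot(inherits(params, "pierluisi_params"), inherits(cond, "gas_conditions"))
  U <- absorber_amount(cond)
  if (is.null(grid)) {
    wl <- params$Cprime$wavelength
    Cp <- params$Cprime$value
  } else {
    wl <- grid
    Cp <- spectrum_at(params$Cprime, grid)
  }
  if (U == 0) return(spectrum(wl, rep(1, length(wl)), "transmittance"))
  arg <- 10^Cp * (cond$p_atm / params$p0)^params$n *
    (params$T0 / cond$T_K)^params$m * U
  t <- exp(-arg^params$a)
  spectrum(wl, pmin(t, 1), "transmittance")
}

## ---- synthetic line list ---------------------------------------------------

# per-band layout constants for the synthetic O2 spectroscopy
band_defaults <- function(band = c("O2A", "O2B")) {
  band <- match.arg(band)
  if (band == "O2A") {
    list(band = band,
         native_window = c(749.5, 777.5),
         line_window   = c(759.6, 770.4),
         branch_split  = 762.0,         # R branch below, P branch above
         anchor        = 760.6,
         channel_span  = c(756.1, 770.6),
         ref_depth     = 0.95,          # 0.22-nm band minimum over 15 m at standard conditions
         column_depth  = 0.15)          # 0.22-nm band-core depth of the down-welling column imprint
  } else {
    list(band = band,
         native_window = c(678.5, 700.0),
         line_window   = c(686.2, 690.8),
         branch_split  = 687.5,
         anchor        = 687.0,
         channel_span  = c(684.5, 694.0),
         ref_depth     = 0.99,
         column_depth  = 0.60)
  }
}

#' Deterministic synthetic O2 line list
#'
#' Builds a reproducible stand-in for the molecular O2 line data of the
#' selected band: Lorentzian lines arranged as two branch envelopes (a short
#' dense branch peaking near the band bottom and a longer decaying branch),
#' with alternating doublet strengths. Strengths are integrated optical depth
#' per km of vertical path at reference conditions (273.16 K, 1 atm), in nm;
#' half-widths are the reference Lorentz half-widths in nm at those
#' conditions. The construction is fully deterministic given
#' `(band, n_lines, seed)`.
#'
#' @param band `"O2A"` (120 lines over 759.6-770.4 nm) or `"O2B"` (60 lines
#'   over 686.2-690.8 nm).
#' @param n_lines Number of lines (default 120 for O2-A, 60 for O2-B).
#' @param seed Integer seed for the (small) deterministic position jitter.
#' @param gamma0 Reference Lorentz half-width in nm at (273.16 K, 1 atm).
#' @return A `data.frame` with columns `center_nm`, `strength`,
#'   `halfwidth_nm`, and attributes `band`, `seed`.
#' @export
o2_line_list <- function(band = c("O2A", "O2B"), n_lines = NULL, seed = 0,
                         gamma0 = 0.035) {
  bd <- band_defaults(band)
  band <- bd$band
  if (is.null(n_lines)) n_lines <- if (band == "O2A") 120L else 60L
  if (n_lines < 2L) stop("need at least two lines")
  if (gamma0 <= 0) stop("half-width must be positive")
  n_r <- max(2L, round(n_lines * 0.4))
  n_p <- n_lines - n_r
  lw <- bd$line_window
  c_r <- seq(lw[1L], bd$branch_split - 0.1, length.out = n_r)
  c_p <- seq(bd$branch_split + 0.1, lw[2L], length.out = n_p)
  # deterministic jitter keeps the list from being artificially periodic
  set.seed(seed)
  c_r <- c_r + stats::runif(n_r, -0.15, 0.15) * mean(diff(c_r))
  c_p <- c_p + stats::runif(n_p, -0.15, 0.15) * mean(diff(c_p))
  # branch strength envelopes: R branch peaks just above the anchor, P branch
  # decays towards the long-wavelength band edge
  peak <- bd$anchor
  s_r <- exp(-((c_r - peak) / (0.45 * (bd$branch_split - lw[1L])))^2)
  s_p <- 0.8 * exp(-(c_p - bd$branch_split) / (0.45 * (lw[2L] - bd$branch_split)))
  centers <- c(c_r, c_p)
  strengths <- c(s_r, s_p)
  # alternating doublet structure
  strengths <- strengths * rep_len(c(1, 0.65), length(strengths))
  o <- order(centers)
  out <- data.frame(center_nm = centers[o], strength = strengths[o],
                    halfwidth_nm = rep(gamma0, n_lines))
  attr(out, "band") <- band
  attr(out, "seed") <- seed
  out
}

#' Monochromatic line-by-line O2 transmittance
#'
#' Beer-Lambert transmittance `t(lambda) = exp[-sum_i tau_i(lambda)]` with
#' area-normalised Lorentzian profiles. Half-widths scale as
#' `gamma = gamma0 (p/p0) (T0/T)^0.7` and strengths as `(T0/T)^m (p/p0)^n`;
#' the slant path is the vertical path divided by the cosine of the view
#' (direction `"up"`) or solar (direction `"down"`) zenith angle.
#'
#' @param grid Wavelength grid (nm); must sample the narrowest scaled
#'   half-width at least 4 times.
#' @param lines A line list from [o2_line_list()].
#' @param cond A [gas_conditions()] (only `T_K`, `p_atm`, `Z_km` are used:
#'   strengths already absorb the reference absorber amount).
#' @param geom A [path_geometry()].
#' @param direction `"up"` (canopy to sensor, slant by vza) or `"down"`
#'   (sensor to canopy, slant by sza).
#' @return A transmittance `spectrum` on `grid`.
#' @export
line_by_line_transmittance <- function(grid, lines, cond,
                                       geom = path_geometry(),
                                       direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(cond, "gas_conditions"))
  if (nrow(lines) == 0L) stop("empty line list")
  k <- .proxsif_constants
  gamma <- lines$halfwidth_nm * (cond$p_atm / k$pier_p0) *
    (k$pier_T0 / cond$T_K)^k$gamma_T_exp
  if (max(diff(grid)) > min(gamma) / 4)
    stop("grid too coarse: must sample the narrowest line half-width 4x")
  mu <- airmass(if (direction == "up") geom$vza else geom$sza)
  scale <- (k$pier_T0 / cond$T_K)^k$pier_m * (cond$p_atm / k$pier_p0)^k$pier_n *
    cond$Z_km * mu
  tau <- numeric(length(grid))
  for (i in seq_len(nrow(lines))) {
    tau <- tau + lines$strength[i] * scale * (gamma[i] / pi) /
      ((grid - lines$center_nm[i])^2 + gamma[i]^2)
  }
  spectrum(grid, exp(-tau), "transmittance")
}

# 0.22-nm band-model channel set for a band (used for calibration, Pierluisi
# coefficient fitting and the seasonal analysis)
bandmodel_sensor <- function(band = "O2A", ssi = 0.22) {
  bd <- band_defaults(band)
  pad <- kernel_half_extent(ssi)
  sensor_config(sr_fwhm = ssi, ssi = ssi,
                span = bd$line_window + c(-1.5, 1.5),
                anchor = bd$anchor)
}

native_grid <- function(band = "O2A", step = 0.005) {
  bd <- band_defaults(band)
  make_grid(bd$native_window[1L], bd$native_window[2L], step)
}

#' Calibrate the overall strength scale of a synthetic line list
#'
#' Rescales all line strengths by a common factor such that the minimum of
#' the 0.22-nm-convolved transmittance at the reference conditions equals
#' `target_depth` (to within 1e-4). The operation is idempotent.
#'
#' @param lines A line list from [o2_line_list()].
#' @param target_depth Target band-minimum transmittance, in (0, 1).
#' @param cond_ref Reference [gas_conditions()] (vertical path).
#' @param grid Optional native grid; defaults to the band's 0.005 nm grid.
#' @return The rescaled line list.
#' @export
calibrate_band_depth <- function(lines, target_depth, cond_ref, grid = NULL) {
  if (target_depth <= 0 || target_depth > 1) stop("target depth must be in (0, 1]")
  band <- attr(lines, "band")
  if (target_depth == 1) { lines$strength[] <- 0; return(lines) }
  if (is.null(grid)) grid <- native_grid(band)
  cfg <- bandmodel_sensor(band)
  depth_at <- function(log10s) {
    ll <- lines; ll$strength <- ll$strength * 10^log10s
    t <- line_by_line_transmittance(grid, ll, cond_ref,
                                    path_geometry(sza = 0, vza = 0), "up")
    min(convolve_and_sample(t, cfg)$value)
  }
  f <- function(x) depth_at(x) - target_depth
  lo <- -6; hi <- 6
  if (f(lo) < 0 || f(hi) > 0) stop("target band depth unreachable")
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-11)$root
  lines$strength <- lines$strength * 10^root
  lines
}

#' Fit per-channel Pierluisi coefficients against a reference transmittance
#'
#' Inverts the band model per channel:
#' `C' = log10[(-ln t)^(1/a) / ((p/p0)^n (T0/T)^m U)]`, so that
#' [pierluisi_transmittance()] reproduces `t_ref` exactly at the fitting
#' conditions. Channels with `t_ref = 1` (no absorption) are clamped to a
#' floor coefficient and flagged.
#'
#' @param t_ref A transmittance `spectrum` on ~0.22 nm channels, values in
#'   (0, 1].
#' @param cond The [gas_conditions()] at which `t_ref` was computed (`U > 0`).
#' @param floor_Cprime Clamp value for non-absorbing channels.
#' @return A [pierluisi_params()] object with the fitted `C'` spectrum.
#' @export
fit_pierluisi_coefficients <- function(t_ref, cond, floor_Cprime = -12) {
  stopifnot(is_spectrum(t_ref), inherits(cond, "gas_conditions"))
  U <- absorber_amount(cond)
  if (U <= 0) stop("fitting requires a non-zero absorber amount")
  k <- .proxsif_constants
  t <- t_ref$value
  if (any(t <= 0)) stop("reference transmittance must be positive")
  flagged <- t >= 1 - 1e-12
  denom <- (cond$p_atm / k$pier_p0)^k$pier_n * (k$pier_T0 / cond$T_K)^k$pier_m * U
  Cp <- rep(floor_Cprime, length(t))
  Cp[!flagged] <- log10((-log(t[!flagged]))^(1 / k$pier_a) / denom)
  # C' values are log10 coefficients (typically negative): bypass the
  # transmittance range check of the spectrum constructor
  Cspec <- structure(list(wavelength = t_ref$wavelength, value = Cp,
                          units = "transmittance"), class = "spectrum")
  pierluisi_params(Cspec, flagged = flagged)
}

#' Barometric pressure at sensor height
#'
#' Combines the hydrostatic equation with the ideal gas law for an isothermal
#' layer: `p_sen = p * exp(-g M0 Z / (R0 T))`, so pressure decreases with
#' height. `strict_paper = TRUE` flips the sign of the exponent.
#'
#' @param p_surface Surface pressure in hPa.
#' @param temperature Air temperature in K.
#' @param Z_m Height above the surface in m.
#' @param strict_paper Use the positive-exponent form instead.
#' @return Pressure at height in hPa.
#' @export
#' @examples
#' pressure_at_height(1000, 283, 30)
pressure_at_height <- function(p_surface, temperature, Z_m, strict_paper = FALSE) {
  if (p_surface <= 0 || temperature <= 0) stop("inputs must be positive")
  k <- .proxsif_constants
  s <- if (strict_paper) 1 else -1
  p_surface * exp(s * k$g * k$M0 * Z_m / (k$R0 * temperature))
}

#' Spectrally smooth aerosol transmittance
#'
#' `t_aer(lambda) = exp[-aot550 (lambda/550)^(-angstrom) (path/H_aer)/cos(angle)]`
#' with the Angstrom exponent and aerosol scale height as configuration; the
#' result has no structure finer than ~10 nm.
#'
#' @param grid Wavelength grid (nm).
#' @param aot550 Aerosol optical thickness of the total column at 550 nm.
#' @param geom A [path_geometry()].
#' @param direction `"up"` or `"down"` (selects vza or sza for the slant).
#' @param angstrom Angstrom exponent (default 1.3).
#' @param H_aer_m Aerosol scale height in m (default 2000).
#' @return A transmittance `spectrum`.
#' @export
aerosol_transmittance <- function(grid, aot550, geom = path_geometry(),
                                  direction = c("up", "down"),
                                  angstrom = 1.3, H_aer_m = 2000) {
  direction <- match.arg(direction)
  if (aot550 < 0) stop("aot550 must be non-negative")
  mu <- airmass(if (direction == "up") geom$vza else geom$sza)
  tau <- aot550 * (grid / 550)^(-angstrom) * (geom$height_m / H_aer_m) * mu
  spectrum(grid, exp(-tau), "transmittance")
}

#' Total path transmittance
#'
#' Pointwise product of the molecular O2 and aerosol transmittances on a
#' common grid. The O2-only, aerosol-only and total variants are all exposed
#' so that correction set-ups using each of them can be compared.
#'
#' @param tO2,taer Transmittance `spectrum` objects on a common grid.
#' @return A transmittance `spectrum`.
#' @export
total_transmittance <- function(tO2, taer) {
  stopifnot(is_spectrum(tO2), is_spectrum(taer))
  check_common_grid(tO2, taer)
  spectrum(tO2$wavelength, tO2$value * taer$value, "transmittance")
}

## ---- calibrated defaults (cached) -----------------------------------------

#' Default calibrated line list for a band
#'
#' The packaged synthetic O2 spectroscopy: [o2_line_list()] rescaled with
#' [calibrate_band_depth()] so that the 0.22-nm-convolved band minimum over a
#' vertical 15 m path at 288.15 K / 1013.25 hPa equals the band's reference
#' depth (0.95 for O2-A, 0.99 for O2-B). Results are cached per session.
#'
#' @param band `"O2A"` or `"O2B"`.
#' @return A calibrated line list `data.frame`.
#' @export
default_line_list <- function(band = c("O2A", "O2B")) {
  band <- match.arg(band)
  key <- paste0("lines_", band)
  if (!is.null(.proxsif_cache[[key]])) return(.proxsif_cache[[key]])
  bd <- band_defaults(band)
  cond_ref <- gas_conditions(288.15, 1013.25, Z_km = 0.015)
  ll <- calibrate_band_depth(o2_line_list(band), bd$ref_depth, cond_ref)
  .proxsif_cache[[key]] <- ll
  ll
}

# conditions representing the O2 column above the sensor (mass-weighted
# representative temperature and pressure; effective path calibrated below)
column_conditions <- function(Z_km) {
  gas_conditions(240, 0.55, Z_km = Z_km, pressure_units = "atm")
}

#' Effective column path for the down-welling irradiance imprint
#'
#' The down-welling solar irradiance reaching the sensor carries the O2
#' absorption of the whole atmospheric column. The column is represented by
#' the same synthetic line list evaluated at column-representative conditions
#' (240 K, 0.55 atm), with an effective absorber path calibrated so that the
#' 0.22-nm-convolved vertical band-core transmittance equals the band's
#' nominal column depth (0.15 for O2-A, 0.6 for O2-B). Cached per session.
#'
#' @param band `"O2A"` or `"O2B"`.
#' @return Effective vertical path in km.
#' @export
column_path_km <- function(band = c("O2A", "O2B")) {
  band <- match.arg(band)
  key <- paste0("colZ_", band)
  if (!is.null(.proxsif_cache[[key]])) return(.proxsif_cache[[key]])
  bd <- band_defaults(band)
  lines <- default_line_list(band)
  grid <- native_grid(band)
  cfg <- bandmodel_sensor(band)
  f <- function(logZ) {
    t <- line_by_line_transmittance(grid, lines, column_conditions(10^logZ),
                                    path_geometry(sza = 0, vza = 0), "down")
    min(convolve_and_sample(t, cfg)$value) - bd$column_depth
  }
  root <- stats::uniroot(f, c(-4, 3), tol = 1e-10)$root
  .proxsif_cache[[paste0("colZ_", band)]] <- 10^root
  10^root
}
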