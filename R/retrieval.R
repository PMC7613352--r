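## SIF estimators: direct isolation with known reflectance, the FLD family
## (FLD/3FLD/iFLD) and its O2-compensated form, the spectral fitting method
## (SFM), its first-order O2-compensated form, and the convolution-consistent
## SFM that rebuilds and convolves the forward model at every iteration.

#' FLD band set
#'
#' @param lambda_in In-band channel wavelength (nm), default 760.6 (the O2-A
#'   band bottom).
#' @param lambda_out Out-of-band channel wavelength(s): one channel for
#'   FLD/iFLD, two shoulder channels bracketing the band for 3FLD.
#' @return An object of class `"fld_band_set"`.
#' @export
fld_band_set <- function(lambda_in = 760.6, lambda_out = c(758.0, 768.0)) {
  if (!length(lambda_out) %in% 1:2) stop("lambda_out must have 1 or 2 channels")
  if (length(lambda_out) == 2L &&
      !(min(lambda_out) < lambda_in && max(lambda_out) > lambda_in))
    stop("3FLD shoulders must bracket the in-band channel")
  structure(list(lambda_in = lambda_in, lambda_out = sort(lambda_out)),
            class = "fld_band_set")
}

#' Spectral-variation coefficients for the iFLD formulation
#'
#' `alpha_R = rho_out / rho_in` and `alpha_F = F_out / F_in`; both equal to 1
#' recovers the plain FLD/3FLD.
#'
#' @param alpha_R,alpha_F Positive scalars.
#' @return An object of class `"alpha_coefficients"`.
#' @export
alpha_coefficients <- function(alpha_R = 1, alpha_F = 1) {
  if (alpha_R <= 0 || alpha_F <= 0) stop("alpha coefficients must be positive")
  structure(list(alpha_R = alpha_R, alpha_F = alpha_F),
            class = "alpha_coefficients")
}

# locate the channel index matching a wavelength: the nearest channel centre,
# provided it lies within one sampling step of the request
channel_index <- function(x, lambda) {
  i <- which.min(abs(x$wavelength - lambda))
  step <- if (length(x$wavelength) > 1L) min(diff(x$wavelength)) else Inf
  if (abs(x$wavelength[i] - lambda) > step + 1e-9)
    stop(sprintf("no channel at %.4f nm in the sensor's channel set", lambda))
  i
}

# in-band / out-of-band (interpolated for 3FLD) values of a channelised spectrum
fld_in_out <- function(x, bands) {
  i_in <- channel_index(x, bands$lambda_in)
  if (length(bands$lambda_out) == 1L) {
    i_out <- channel_index(x, bands$lambda_out)
    v_out <- x$value[i_out]
  } else {
    i1 <- channel_index(x, bands$lambda_out[1L])
    i2 <- channel_index(x, bands$lambda_out[2L])
    w1 <- x$wavelength[i1]; w2 <- x$wavelength[i2]
    # linear interpolation of the two shoulder channels to lambda_in
    f <- (bands$lambda_in - w1) / (w2 - w1)
    v_out <- (1 - f) * x$value[i1] + f * x$value[i2]
  }
  list(v_in = x$value[i_in], v_out = v_out)
}

#' FLD-family SIF estimate at top-of-canopy level
#'
#' Evaluates `F = (alpha_R Ebar_out Lbar_in - Ebar_in Lbar_out) /
#' (alpha_R Ebar_out - alpha_F Ebar_in)`. With one out-of-band channel and
#' unit alphas this is the FLD; with two shoulder channels (linearly
#' interpolated to the in-band wavelength) it is the 3FLD; supplying
#' non-unit alphas gives the iFLD.
#'
#' @param E_bar Channelised at-surface irradiance `spectrum`.
#' @param L_bar Channelised top-of-canopy radiance `spectrum`.
#' @param bands A [fld_band_set()].
#' @param alpha An [alpha_coefficients()].
#' @return Estimated SIF (scalar, mW m-2 sr-1 nm-1).
#' @export
fld_family <- function(E_bar, L_bar, bands = fld_band_set(),
                       alpha = alpha_coefficients()) {
  stopifnot(is_spectrum(E_bar), is_spectrum(L_bar))
  E <- fld_in_out(E_bar, bands)
  L <- fld_in_out(L_bar, bands)
  den <- alpha$alpha_R * E$v_out - alpha$alpha_F * E$v_in
  if (abs(den) <= 1e-9 * abs(E$v_out))
    stop("degenerate FLD denominator: alpha_R*E_out ~ alpha_F*E_in")
  (alpha$alpha_R * E$v_out * L$v_in - E$v_in * L$v_out) / den
}

#' O2-compensated FLD-family SIF estimate at sensor level
#'
#' Compensates the at-sensor quantities for the canopy-to-sensor O2
#' transmittance channel by channel and evaluates the FLD-family formula on
#' the corrected values: `Lbar = L / t_up`, `Ebar = E * t_down` (the latter
#' omitted when the irradiance is already measured at canopy level,
#' `E_is_toc = TRUE`). With all transmittances equal to 1 this reduces
#' exactly to [fld_family()]. `strict_paper = TRUE` instead evaluates the
#' printed compensated expression in which the in-band radiance is
#' multiplied (not divided) by the upward transmittance.
#'
#' @param E Channelised irradiance `spectrum` (at sensor level, or at canopy
#'   level with `E_is_toc = TRUE`).
#' @param L Channelised at-sensor radiance `spectrum`.
#' @param t_up,t_down Channelised upward/downward transmittance spectra.
#' @param bands A [fld_band_set()].
#' @param alpha An [alpha_coefficients()].
#' @param E_is_toc Irradiance already at canopy level (skip the `t_down`
#'   correction).
#' @param strict_paper Evaluate the printed formulation verbatim.
#' @return Estimated SIF (scalar).
#' @export
fld_o2 <- function(E, L, t_up, t_down, bands = fld_band_set(),
                   alpha = alpha_coefficients(), E_is_toc = FALSE,
                   strict_paper = FALSE) {
  stopifnot(is_spectrum(E), is_spectrum(L), is_spectrum(t_up))
  if (any(t_up$value <= 0)) stop("zero upward transmittance channel")
  if (!E_is_toc && any(t_down$value <= 0)) stop("zero downward transmittance channel")
  if (strict_paper) {
    Ei <- fld_in_out(E, bands); Li <- fld_in_out(L, bands)
    tu <- fld_in_out(t_up, bands)
    td <- if (E_is_toc) list(v_in = 1, v_out = 1) else fld_in_out(t_down, bands)
    den <- Ei$v_out * alpha$alpha_R * td$v_out - Ei$v_in * alpha$alpha_F * td$v_in
    if (abs(den) <= 1e-9 * abs(Ei$v_out)) stop("degenerate FLD denominator")
    return((Li$v_in * tu$v_in * alpha$alpha_R * Ei$v_out * td$v_out -
              Li$v_out * tu$v_out * Ei$v_in * td$v_in) / den)
  }
  L_corr <- spectrum(L$wavelength, L$value / t_up$value, "radiance")
  E_corr <- if (E_is_toc) E else
    spectrum(E$wavelength, E$value * t_down$value, "irradiance")
  fld_family(E_corr, L_corr, bands, alpha)
}

#' iFLD spectral-variation coefficients from apparent reflectance
#'
#' Estimates `alpha_R` as the ratio of a smooth (absorption-masked) fit of the
#' apparent reflectance at the out-of-band and in-band wavelengths, and
#' `alpha_F` from a reference SIF shape when available (1 otherwise).
#'
#' @param rho_app Channelised apparent reflectance `spectrum`.
#' @param bands A [fld_band_set()].
#' @param mask_t Optional channelised transmittance used to exclude absorbed
#'   channels (threshold 0.995) from the smooth fit.
#' @param F_ref Optional reference SIF `spectrum` for `alpha_F`.
#' @return An [alpha_coefficients()].
#' @export
ifld_alpha <- function(rho_app, bands = fld_band_set(), mask_t = NULL,
                       F_ref = NULL) {
  wl <- rho_app$wavelength
  keep <- rep(TRUE, length(wl))
  if (!is.null(mask_t)) keep <- mask_t$value >= 0.995
  if (sum(keep) < 5L) stop("too few unabsorbed channels for the smooth fit")
  fit <- stats::lm(v ~ poly(w, 3, raw = TRUE),
                   data = data.frame(w = wl[keep], v = rho_app$value[keep]))
  pr <- function(l) stats::predict(fit, newdata = data.frame(w = l))
  l_out <- if (length(bands$lambda_out) == 2L) mean(bands$lambda_out) else bands$lambda_out
  aR <- as.numeric(pr(l_out) / pr(bands$lambda_in))
  aF <- 1
  if (!is.null(F_ref)) {
    Fi <- fld_in_out(F_ref, bands)
    if (Fi$v_in > 0) aF <- Fi$v_out / Fi$v_in
  }
  alpha_coefficients(alpha_R = aR, alpha_F = aF)
}

#' Direct SIF isolation with known surface reflectance
#'
#' Applies one of the four measurement set-ups, assuming the reflectance
#' spectrum is known:
#' set-up 1 `F = L/t_corr - Ebar rho / pi` (radiance corrected, irradiance at
#' canopy); 2 `F = L - Ebar rho / pi`; 3 `F = L/t_corr - E rho / pi`
#' (irradiance at sensor); 4 `F = L - E rho / pi`.
#'
#' @param L Channelised at-sensor radiance `spectrum`.
#' @param E_or_Ebar Channelised irradiance: at canopy level for set-ups 1-2,
#'   at sensor level for 3-4.
#' @param rho_true Channelised reference reflectance `spectrum`.
#' @param t_corr Channelised upward transmittance used for the correction
#'   (required for set-ups 1 and 3; typically the O2-only transmittance, or
#'   the total path transmittance).
#' @param setup Integer 1-4.
#' @return Estimated SIF `spectrum` on the channels.
#' @export
direct_isolation <- function(L, E_or_Ebar, rho_true, t_corr = NULL,
                             setup = 1L) {
  setup <- as.integer(setup)
  if (!setup %in% 1:4) stop("setup must be 1, 2, 3 or 4")
  stopifnot(is_spectrum(L), is_spectrum(E_or_Ebar), is_spectrum(rho_true))
  corrected <- setup %in% c(1L, 3L)
  if (corrected && is.null(t_corr))
    stop("t_corr is required for set-ups 1 and 3")
  Lc <- if (corrected) L$value / t_corr$value else L$value
  Fv <- Lc - E_or_Ebar$value * rho_true$value / pi
  spectrum(L$wavelength, Fv, "radiance")
}

## ---- SFM -------------------------------------------------------------------

#' SFM configuration
#'
#' @param window Spectral fitting interval in nm (default 759.3-767.5).
#' @param deg_rho Reflectance polynomial degree (default 3, cubic).
#' @param deg_F Fluorescence polynomial degree (default 2, quadratic).
#' @param max_iter Maximum optimiser iterations.
#' @param step_tol,residual_tol Optimiser stopping tolerances (relative step
#'   and relative residual reduction).
#' @param first_guess_distortion Fractional distortion applied to the
#'   first-guess fluorescence coefficients (default 0.10).
#' @return An object of class `"sfm_config"`.
#' @export
sfm_config <- function(window = c(759.3, 767.5), deg_rho = 3, deg_F = 2,
                       max_iter = 200, step_tol = 1e-10, residual_tol = 1e-12,
                       first_guess_distortion = 0.10) {
  if (deg_rho < 0 || deg_F < 0) stop("polynomial degrees must be non-negative")
  if (window[1L] >= window[2L]) stop("invalid window")
  structure(list(window = window, deg_rho = deg_rho, deg_F = deg_F,
                 max_iter = max_iter, step_tol = step_tol,
                 residual_tol = residual_tol,
                 first_guess_distortion = first_guess_distortion),
            class = "sfm_config")
}

# wavelengths centred/scaled to [-1, 1] inside the window, for conditioning
sfm_basis_x <- function(wl, cfg) {
  (wl - mean(cfg$window)) / (diff(cfg$window) / 2)
}

sfm_design <- function(wl, cfg) {
  x <- sfm_basis_x(wl, cfg)
  list(P_rho = outer(x, 0:cfg$deg_rho, `^`),
       P_F   = outer(x, 0:cfg$deg_F, `^`))
}

poly_fit_coef <- function(wl, v, degree, cfg) {
  X <- outer(sfm_basis_x(wl, cfg), 0:degree, `^`)
  as.numeric(qr.solve(X, v))
}

#' First-guess SFM coefficients
#'
#' The fluorescence first guess is a quadratic fit to a reference SIF
#' spectrum with every coefficient multiplied by `(1 + distortion)`; the
#' reflectance first guess is a cubic fit to the apparent reflectance on the
#' channels not affected by absorption (native transmittance above 0.995
#' everywhere inside the channel's resolution element).
#'
#' @param F_ref Channelised reference SIF `spectrum`.
#' @param rho_app Channelised apparent reflectance `spectrum`.
#' @param cfg An [sfm_config()].
#' @param mask_t Optional native-resolution short-path transmittance
#'   `spectrum` used to identify absorbed channels (any native value below
#'   0.995 inside the channel's resolution element excludes the channel);
#'   `NULL` uses all channels.
#' @param sensor Optional [sensor_config()] (needed to map the native mask to
#'   channels).
#' @param distortion Fractional coefficient distortion (defaults to the
#'   config value).
#' @param col_t Optional native-resolution column transmittance; channels
#'   whose channel-mean column transmittance falls below 0.95 are excluded
#'   (fluorescence in-filling distorts the apparent reflectance there).
#' @return A list with elements `x_rho` and `x_F` (coefficient vectors in the
#'   scaled window basis).
#' @export
sfm_first_guess <- function(F_ref, rho_app, cfg = sfm_config(), mask_t = NULL,
                            sensor = NULL, distortion = NULL, col_t = NULL) {
  if (is.null(distortion)) distortion <- cfg$first_guess_distortion
  win <- cfg$window
  inw <- function(x) x$wavelength >= win[1L] - 1e-9 & x$wavelength <= win[2L] + 1e-9
  kF <- inw(F_ref)
  x_F <- poly_fit_coef(F_ref$wavelength[kF], F_ref$value[kF], cfg$deg_F, cfg) *
    (1 + distortion)
  # the reflectance guess uses the region around the band, excluding absorbed
  # channels (the smooth fit is then evaluated inside the window)
  keep <- rep(TRUE, length(rho_app$wavelength))
  half <- if (!is.null(sensor)) max(sensor$ssi, sensor$sr_fwhm) / 2 else 0.25
  if (!is.null(mask_t)) {
    absorbed <- vapply(rho_app$wavelength, function(cc) {
      sel <- abs(mask_t$wavelength - cc) <= half
      any(mask_t$value[sel] < 0.995)
    }, logical(1L))
    keep <- keep & !absorbed
  }
  if (!is.null(col_t)) {
    infilled <- vapply(rho_app$wavelength, function(cc) {
      sel <- abs(col_t$wavelength - cc) <= half
      mean(col_t$value[sel]) < 0.95
    }, logical(1L))
    keep <- keep & !infilled
  }
  if (sum(keep) < cfg$deg_rho + 1L)
    stop("too few out-of-band channels for the reflectance first guess")
  x_rho <- poly_fit_coef(rho_app$wavelength[keep], rho_app$value[keep],
                         cfg$deg_rho, cfg)
  list(x_rho = x_rho, x_F = x_F)
}

retrieval_result <- function(F_est, rho_est, fit, cfg, F_true = NULL) {
  rel <- NULL
  if (!is.null(F_true)) {
    check_common_grid(F_est, F_true)
    rel <- 100 * (F_est$value - F_true$value) / F_true$value
  }
  structure(list(F_est = F_est, rho_est = rho_est,
                 coefficients = fit$par,
                 diagnostics = list(iterations = fit$niter,
                                    residual = fit$deviance,
                                    converged = fit$converged,
                                    message = fit$message),
                 rel_error_pct = rel, window = cfg$window),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  i760 <- which.min(abs(x$F_est$wavelength - 760.6))
  cat(sprintf("<retrieval_result> F(%.2f nm) = %.4f; %d iterations, residual %.3g%s\n",
              x$F_est$wavelength[i760], x$F_est$value[i760],
              x$diagnostics$iterations, x$diagnostics$residual,
              if (isTRUE(x$diagnostics$converged)) "" else " (not converged)"))
  invisible(x)
}

# shared Levenberg-Marquardt driver over the (rho, F) coefficient vector;
# the model families are linear in the coefficients, so the (constant)
# analytic Jacobian is supplied whenever available
sfm_minimize <- function(residual_fn, start, cfg, jacobian_fn = NULL) {
  fit <- minpack.lm::nls.lm(
    par = start, fn = residual_fn, jac = jacobian_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = min(cfg$max_iter, 1024L),
      ftol = cfg$residual_tol, ptol = cfg$step_tol))
  list(par = fit$par, niter = fit$niter, deviance = fit$deviance,
       converged = fit$info %in% 1:4, message = fit$message)
}

split_par <- function(par, cfg) {
  n_rho <- cfg$deg_rho + 1L
  list(x_rho = par[seq_len(n_rho)], x_F = par[-seq_len(n_rho)])
}

#' Spectral fitting method at top-of-canopy level
#'
#' Least-squares decoupling of reflectance and fluorescence over the fitting
#' window: minimises `Lbar - (rho_MOD * Ebar / pi + F_MOD)` over the
#' polynomial coefficients of `rho_MOD` (cubic by default) and `F_MOD`
#' (quadratic by default), with unweighted residuals and no positivity
#' constraint on the modelled functions.
#'
#' @param E_bar Channelised at-surface irradiance `spectrum`.
#' @param L_bar Channelised top-of-canopy radiance `spectrum`.
#' @param cfg An [sfm_config()].
#' @param first_guess Optional list with `x_rho`, `x_F` (see
#'   [sfm_first_guess()]); zeros otherwise.
#' @param F_true Optional channelised reference SIF for error diagnostics.
#' @return A `retrieval_result` with `F_est` and `rho_est` on the window
#'   channels.
#' @export
sfm_fit <- function(E_bar, L_bar, cfg = sfm_config(), first_guess = NULL,
                    F_true = NULL) {
  stopifnot(is_spectrum(E_bar), is_spectrum(L_bar))
  check_common_grid(E_bar, L_bar)
  win <- cfg$window
  keep <- E_bar$wavelength >= win[1L] - 1e-9 & E_bar$wavelength <= win[2L] + 1e-9
  n_par <- cfg$deg_rho + cfg$deg_F + 2L
  if (sum(keep) < n_par) stop("not enough channels in the fitting window")
  wl <- E_bar$wavelength[keep]
  D <- sfm_design(wl, cfg)
  Ev <- E_bar$value[keep]; Lv <- L_bar$value[keep]
  # same floating-point association as the compensated variants, so the
  # t == 1 reduction is exact
  resid <- function(par) {
    p <- split_par(par, cfg)
    Lv - (Ev / pi * drop(D$P_rho %*% p$x_rho) + drop(D$P_F %*% p$x_F))
  }
  jac <- function(par) -cbind(Ev / pi * D$P_rho, D$P_F)
  start <- if (is.null(first_guess)) rep(0, n_par) else
    c(first_guess$x_rho, first_guess$x_F)
  fit <- sfm_minimize(resid, start, cfg, jac)
  p <- split_par(fit$par, cfg)
  F_est <- spectrum(wl, drop(D$P_F %*% p$x_F), "radiance")
  rho_est <- structure(list(wavelength = wl,
                            value = drop(D$P_rho %*% p$x_rho),
                            units = "reflectance"), class = "spectrum")
  Ft <- if (is.null(F_true)) NULL else spectrum_window(F_true, win)
  retrieval_result(F_est, rho_est, fit, cfg, Ft)
}

#' First-order O2-compensated SFM at sensor level
#'
#' Minimises `L - (E t_down / pi * rho_MOD + F_MOD) * t_up` over the window
#' channels, with all spectra individually channelised. This deliberately
#' embodies the first-order scheme that multiplies already-convolved
#' atmospheric functions, so that its resolution-dependent bias can be
#' measured; with all transmittances equal to 1 it reduces exactly to
#' [sfm_fit()].
#'
#' @param E Channelised irradiance (at sensor, or at canopy with
#'   `E_is_toc = TRUE`).
#' @param L Channelised at-sensor radiance.
#' @param t_down,t_up Channelised transmittances.
#' @param cfg An [sfm_config()].
#' @param first_guess Optional first-guess coefficients.
#' @param E_is_toc Skip the `t_down` factor (irradiance already at canopy).
#' @param F_true Optional reference SIF for diagnostics.
#' @return A `retrieval_result`.
#' @export
sfm_fit_o2 <- function(E, L, t_down, t_up, cfg = sfm_config(),
                       first_guess = NULL, E_is_toc = FALSE, F_true = NULL) {
  stopifnot(is_spectrum(E), is_spectrum(L), is_spectrum(t_up))
  check_common_grid(E, L)
  win <- cfg$window
  keep <- E$wavelength >= win[1L] - 1e-9 & E$wavelength <= win[2L] + 1e-9
  n_par <- cfg$deg_rho + cfg$deg_F + 2L
  if (sum(keep) < n_par) stop("not enough channels in the fitting window")
  wl <- E$wavelength[keep]
  D <- sfm_design(wl, cfg)
  Ebar_v <- if (E_is_toc) E$value[keep] else E$value[keep] * t_down$value[keep]
  Lv <- L$value[keep]; tu <- t_up$value[keep]
  if (any(tu <= 0)) stop("zero upward transmittance channel")
  resid <- function(par) {
    p <- split_par(par, cfg)
    Lv - (Ebar_v / pi * drop(D$P_rho %*% p$x_rho) + drop(D$P_F %*% p$x_F)) * tu
  }
  jac <- function(par) -cbind(tu * (Ebar_v / pi) * D$P_rho, tu * D$P_F)
  start <- if (is.null(first_guess)) rep(0, n_par) else
    c(first_guess$x_rho, first_guess$x_F)
  fit <- sfm_minimize(resid, start, cfg, jac)
  p <- split_par(fit$par, cfg)
  F_est <- spectrum(wl, drop(D$P_F %*% p$x_F), "radiance")
  rho_est <- structure(list(wavelength = wl,
                            value = drop(D$P_rho %*% p$x_rho),
                            units = "reflectance"), class = "spectrum")
  Ft <- if (is.null(F_true)) NULL else spectrum_window(F_true, win)
  retrieval_result(F_est, rho_est, fit, cfg, Ft)
}

#' Fit the atmospheric state from at-sensor irradiance
#'
#' Estimates the effective column absorber path by minimising the channel
#' residuals between the modelled irradiance (smooth solar baseline times the
#' column O2 transmittance, channelised with the sensor's ISRF) and the
#' measured channelised irradiance. With noise-free self-consistent input the
#' scaling is recovered essentially exactly.
#'
#' @param E_measured Channelised at-sensor irradiance `spectrum`.
#' @param sensor The [sensor_config()] that produced `E_measured`.
#' @param lines Calibrated line list (defaults to the band's).
#' @param geom A [path_geometry()] (the solar zenith angle slants the column).
#' @param band `"O2A"` or `"O2B"`.
#' @param bounds Search interval for the column path scaling (relative to the
#'   band's nominal column path).
#' @param residual_tol Flag threshold on the root-mean-square relative
#'   residual.
#' @return A list with `scale` (relative to the nominal column path),
#'   `Z_col_km`, `rms_rel_residual`, `flagged` (poor fit or bound-clipped).
#' @export
fit_atmosphere <- function(E_measured, sensor, lines = NULL,
                           geom = path_geometry(), band = "O2A",
                           bounds = c(0, 5), residual_tol = 1e-3) {
  stopifnot(is_spectrum(E_measured), inherits(sensor, "sensor_config"))
  if (is.null(lines)) lines <- default_line_list(band)
  grid <- native_grid(band)
  E0 <- synth_solar_irradiance(grid)
  Z0 <- column_path_km(band)
  wl_keep <- E_measured$wavelength
  model_E <- function(s) {
    tc <- if (s > 0)
      line_by_line_transmittance(grid, lines, column_conditions(s * Z0), geom, "down")
    else spectrum(grid, rep(1, length(grid)), "transmittance")
    Em <- convolve_and_sample(spectrum(grid, E0$value * tc$value, "irradiance"),
                              sensor)
    spectrum_at(Em, wl_keep)
  }
  obj <- function(s) sum((model_E(s) - E_measured$value)^2)
  opt <- stats::optimize(obj, interval = bounds, tol = 1e-9)
  s <- opt$minimum
  rms <- sqrt(mean(((model_E(s) - E_measured$value) / E_measured$value)^2))
  at_bound <- min(s - bounds[1L], bounds[2L] - s) < 1e-6 * diff(range(bounds))
  list(scale = s, Z_col_km = s * Z0, rms_rel_residual = rms,
       flagged = at_bound || rms > residual_tol,
       band = band, lines = lines, geom = geom)
}

#' Native atmospheric functions from a fitted atmospheric state
#'
#' Reconstructs, at native resolution, the at-surface irradiance and the
#' upward transmittance that the convolution-consistent SFM needs: the smooth
#' solar baseline times the fitted column imprint, propagated through the
#' short-path downward transmittance for the known tower geometry and
#' measured meteorological conditions.
#'
#' @param fit Result of [fit_atmosphere()].
#' @param height_m Sensor height above the canopy in m.
#' @param temperature Air temperature in K.
#' @param pressure Surface pressure in hPa.
#' @return A list with native `spectrum` fields `E_bar`, `t_up`, `t_down`,
#'   `t_col`.
#' @export
model_atmosphere <- function(fit, height_m, temperature = 288.15,
                             pressure = 1013.25) {
  grid <- native_grid(fit$band)
  geom <- path_geometry(height_m = height_m, sza = fit$geom$sza,
                        vza = fit$geom$vza)
  cond <- gas_conditions(temperature, pressure, Z_km = height_m / 1000)
  E0 <- synth_solar_irradiance(grid)
  t_col <- if (fit$Z_col_km > 0)
    line_by_line_transmittance(grid, fit$lines,
                               column_conditions(fit$Z_col_km), geom, "down")
  else spectrum(grid, rep(1, length(grid)), "transmittance")
  if (height_m > 0) {
    t_up <- line_by_line_transmittance(grid, fit$lines, cond, geom, "up")
    t_down <- line_by_line_transmittance(grid, fit$lines, cond, geom, "down")
  } else {
    ones <- rep(1, length(grid))
    t_up <- t_down <- spectrum(grid, ones, "transmittance")
  }
  E_bar <- spectrum(grid, E0$value * t_col$value * t_down$value, "irradiance")
  list(E_bar = E_bar, t_up = t_up, t_down = t_down, t_col = t_col)
}

#' Convolution-consistent SFM with a modelled atmosphere
#'
#' The airborne-style scheme: reflectance and fluorescence are native-grid
#' polynomials, the forward model `(Ebar / pi * rho_MOD + F_MOD) * t_up` is
#' built on the native grid with the modelled atmospheric functions and
#' convolved/channelised with the sensor's ISRF at every evaluation of the
#' minimisation, so no algebra is ever performed between individually
#' convolved spectra.
#'
#' @param L Channelised at-sensor radiance `spectrum`.
#' @param atm Native atmospheric functions from [model_atmosphere()] (or a
#'   list with `E_bar` and `t_up` native spectra).
#' @param sensor The [sensor_config()] of the measurement.
#' @param cfg An [sfm_config()].
#' @param first_guess Optional first-guess coefficients.
#' @param F_true Optional channelised reference SIF for diagnostics.
#' @return A `retrieval_result`; `F_est`/`rho_est` are reported on the window
#'   channels (evaluated from the native-grid polynomials).
#' @export
sfm_fit_convolved <- function(L, atm, sensor, cfg = sfm_config(),
                              first_guess = NULL, F_true = NULL) {
  stopifnot(is_spectrum(L), inherits(sensor, "sensor_config"))
  E_bar <- atm$E_bar; t_up <- atm$t_up
  check_common_grid(E_bar, t_up)
  step <- max(diff(E_bar$wavelength))
  if (step > sensor$sr_fwhm / 5 && 2 * kernel_half_extent(sensor$sr_fwhm) >= step)
    stop("native atmospheric grid must be at least 5x finer than the SR")
  win <- cfg$window
  keep <- L$wavelength >= win[1L] - 1e-9 & L$wavelength <= win[2L] + 1e-9
  n_par <- cfg$deg_rho + cfg$deg_F + 2L
  if (sum(keep) < n_par) stop("not enough channels in the fitting window")
  wl_ch <- L$wavelength[keep]
  Lv <- L$value[keep]
  # restricted copy of the user's sensor over the window channels (any
  # SR/SSI advisory warning was already raised at construction time)
  cfg_win <- suppressWarnings(
    sensor_config(sensor$sr_fwhm, sensor$ssi, channel_centers = wl_ch))
  # native design matrices over the kernel-extended window
  pad <- kernel_half_extent(sensor$sr_fwhm)
  sel <- E_bar$wavelength >= win[1L] - pad - 1e-9 &
    E_bar$wavelength <= win[2L] + pad + 1e-9
  wl_nat <- E_bar$wavelength[sel]
  D <- sfm_design(wl_nat, cfg)
  Ev <- E_bar$value[sel]; tu <- t_up$value[sel]
  # the model is linear in the coefficients: channelise each native basis
  # function once, so that the residual and its (constant) Jacobian are
  # evaluated exactly and cheaply at every iteration
  basis_nat <- cbind(Ev / pi * D$P_rho, D$P_F) * tu
  A <- vapply(seq_len(ncol(basis_nat)), function(j)
    convolve_and_sample(spectrum(wl_nat, basis_nat[, j], "radiance"),
                        cfg_win)$value,
    numeric(length(wl_ch)))
  resid <- function(par) Lv - drop(A %*% par)
  jac <- function(par) -A
  start <- if (is.null(first_guess)) rep(0, n_par) else
    c(first_guess$x_rho, first_guess$x_F)
  fit <- sfm_minimize(resid, start, cfg, jac)
  p <- split_par(fit$par, cfg)
  Dch <- sfm_design(wl_ch, cfg)
  F_est <- spectrum(wl_ch, drop(Dch$P_F %*% p$x_F), "radiance")
  rho_est <- structure(list(wavelength = wl_ch,
                            value = drop(Dch$P_rho %*% p$x_rho),
                            units = "reflectance"), class = "spectrum")
  Ft <- if (is.null(F_true)) NULL else spectrum_window(F_true, win)
  retrieval_result(F_est, rho_est, fit, cfg, Ft)
}
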