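## Physical constants and fixed model parameters, collected in one place so the
## CLI manifest can log them and so strict-paper toggles have a single source.

.proxsif_constants <- list(
  g       = 9.80665,     # standard gravity [m s-2]
  M0      = 0.0289644,   # molar mass of dry air [kg mol-1]
  R0      = 8.31446,     # ideal gas constant [J mol-1 K-1]
  R_dry   = 287.0474,    # specific gas constant of dry air [J kg-1 K-1]
  atm_hPa = 1013.25,     # 1 atm in hPa
  # Pierluisi band-model parameters for O2 (dimensionless unless noted)
  pier_a  = 0.5641,
  pier_m  = 0.9353,
  pier_n  = 0.1936,
  pier_T0 = 273.16,      # K
  pier_p0 = 1,           # atm
  U_coef  = 0.7732e-4,   # absorber amount coefficient [atm cm / (ppmv g m-3 km)]
  M_O2    = 209460,      # O2 concentration in dry air [ppmv]
  # half-width air-broadening temperature exponent
  gamma_T_exp = 0.7
)

#' Physical constants used throughout the toolkit
#'
#' Returns the named list of physical constants and fixed empirical band-model
#' parameters (standard gravity, molar mass of dry air, the ideal gas constant,
#' the O2 band-model exponents and reference conditions, the absorber-amount
#' coefficient and the O2 mixing ratio).
#'
#' @return Named list of constants.
#' @export
#' @examples
#' proxsif_constants()$g
proxsif_constants <- function() .proxsif_constants

# package-local cache for calibrated line lists and fitted band-model
# coefficients (all deterministic, so caching is purely an optimisation)
.proxsif_cache <- new.env(parent = emptyenv())
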