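## Readers/writers for the plain-text exchange formats: 2-column spectrum
## CSV, line-list CSV, meteorological series CSV and YAML run configuration.

.unit_header <- c(radiance = "radiance_mW_m2_sr_nm",
                  irradiance = "irradiance_mW_m2_nm",
                  transmittance = "transmittance",
                  reflectance = "reflectance")

#' Write a spectrum to a two-column CSV
#'
#' The header is `wavelength_nm,<quantity>` where the quantity tag encodes
#' the units; round-trips preserve values to better than 1e-9 relative.
#'
#' @param x A `spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(is_spectrum(x))
  df <- data.frame(wavelength_nm = x$wavelength, value = x$value)
  names(df)[2L] <- .unit_header[[x$units]]
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum from a two-column CSV
#'
#' @param path Input file path (`wavelength_nm,<quantity>` header).
#' @param expected_units Optional units check (`"radiance"`, `"irradiance"`,
#'   `"transmittance"`, `"reflectance"`).
#' @return A `spectrum`.
#' @export
read_spectrum <- function(path, expected_units = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) != 2L) stop("spectrum CSV must have exactly two columns")
  if (names(df)[1L] != "wavelength_nm")
    stop("first column must be 'wavelength_nm'")
  units <- names(.unit_header)[match(names(df)[2L], .unit_header)]
  if (is.na(units))
    stop(sprintf("unrecognised quantity header '%s'", names(df)[2L]))
  if (!is.null(expected_units) && units != expected_units)
    stop(sprintf("units mismatch: file has %s, expected %s", units,
                 expected_units))
  wl <- as.numeric(df[[1L]])
  if (anyNA(wl) || anyNA(as.numeric(df[[2L]]))) stop("malformed rows in spectrum CSV")
  dw <- diff(wl)
  # report the 1-based file row (header included)
  if (any(dw == 0))
    stop(sprintf("duplicated wavelength at row %d", which(dw == 0)[1L] + 2L))
  if (any(dw < 0))
    stop(sprintf("descending wavelengths at row %d", which(dw < 0)[1L] + 2L))
  spectrum(wl, as.numeric(df[[2L]]), units)
}

#' Write a line list to CSV
#'
#' @param lines A line list (`center_nm`, `strength`, `halfwidth_nm`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_line_list <- function(lines, path) {
  df <- data.frame(center_nm = lines$center_nm, strength = lines$strength,
                   halfwidth_nm = lines$halfwidth_nm)
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a line list from CSV
#'
#' @param path Input file path.
#' @param band Band tag to attach (`"O2A"` or `"O2B"`).
#' @return A line list `data.frame`.
#' @export
read_line_list <- function(path, band = "O2A") {
  df <- utils::read.csv(path)
  need <- c("center_nm", "strength", "halfwidth_nm")
  if (!all(need %in% names(df)))
    stop("line list CSV must have columns center_nm, strength, halfwidth_nm")
  out <- df[need]
  attr(out, "band") <- band
  out
}

#' Read a meteorological series from CSV
#'
#' Expects columns `doy`, `p_hPa` and either `T_K` or `T_C` (converted by
#' adding 273.15).
#'
#' @param path Input file path.
#' @param sensor_height_m Sensor height metadata to attach.
#' @return A `met_series` data frame.
#' @export
read_met_csv <- function(path, sensor_height_m = 15) {
  df <- utils::read.csv(path)
  if (!"doy" %in% names(df)) stop("missing column 'doy'")
  if (!"p_hPa" %in% names(df)) stop("missing column 'p_hPa'")
  if ("T_K" %in% names(df)) {
    T_K <- df$T_K
  } else if ("T_C" %in% names(df)) {
    T_K <- df$T_C + 273.15
  } else stop("missing temperature column ('T_K' or 'T_C')")
  if (any(df$doy < 1 | df$doy > 365)) stop("doy out of range 1-365")
  if (any(T_K <= 0 | T_K > 350)) stop("temperature out of physical range")
  if (any(df$p_hPa < 300 | df$p_hPa > 1200)) stop("pressure out of physical range")
  out <- data.frame(doy = df$doy, T_K = T_K, p_hPa = df$p_hPa)
  attr(out, "sensor_height_m") <- sensor_height_m
  class(out) <- c("met_series", "data.frame")
  out
}

#' Read a YAML run configuration
#'
#' A flat or nested YAML file holding scene parameters, sensor
#' configurations, retrieval settings and the physical-constants block; the
#' constants block defaults to [proxsif_constants()].
#'
#' @param path YAML file path.
#' @return A named list with class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$constants)) cfg$constants <- proxsif_constants()
  if (is.null(cfg$strict_paper)) cfg$strict_paper <- FALSE
  structure(cfg, class = "run_config")
}

#' Write a run configuration (and manifest) to YAML
#'
#' @param cfg A named list (e.g. from [read_run_config()]).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
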