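# Shared fixtures, built in code and cached for the test run. Scenes are
# deterministic, so caching only saves time.

.px <- new.env()

px_span <- c(756.1, 770.6)   # default O2-A channel span

px_sensor <- function(ssi, sr, span = px_span, anchor = 760.6) {
  sensor_config(sr_fwhm = sr, ssi = ssi, span = span, anchor = anchor)
}

px_scene <- function(height_m, ...) {
  key <- paste0("scene_", height_m, "_", paste(c(...), collapse = "_"))
  if (is.null(.px[[key]])) .px[[key]] <- make_scene(height_m = height_m, ...)
  .px[[key]]
}

px_channels <- function(height_m, ssi, sr) {
  key <- sprintf("ch_%s_%s_%s", height_m, ssi, sr)
  if (is.null(.px[[key]]))
    .px[[key]] <- channelize_scene(px_scene(height_m), px_sensor(ssi, sr))
  .px[[key]]
}

px_grid <- function() {
  if (is.null(.px$grid)) .px$grid <- proxsif:::native_grid("O2A")
  .px$grid
}

px_ones_ch <- function(x) spectrum(x$wavelength, rep(1, length(x$wavelength)),
                                   "transmittance")

# first guess for the SFM from a scene + channelisation
px_first_guess <- function(sc, ch, sensor, cfg = sfm_config()) {
  mask_path <- spectrum(sc$grid,
                        pmin(sc$t_down_O2$value * sc$t_up_O2$value, 1),
                        "transmittance")
  sfm_first_guess(ch$F, apparent_reflectance(ch$L, ch$E), cfg,
                  mask_path, sensor, col_t = sc$t_col)
}
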