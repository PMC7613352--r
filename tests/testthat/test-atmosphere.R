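# O2 transmittance physics: absorber amount, the empirical band model, the
# synthetic line-by-line engine, calibration, pressure and aerosols.

test_that("absorber amount follows the closed form and is linear in path", {
  cond <- gas_conditions(288.15, 1013.25, rho_a = 1225, Z_km = 0.015)
  expect_equal(absorber_amount(cond), 0.7732e-4 * 209460 * 1225 * 0.015,
               tolerance = 1e-12)
  expect_equal(absorber_amount(cond), 297.6, tolerance = 1e-3)
  z0 <- gas_conditions(288.15, 1013.25, Z_km = 0)
  expect_identical(absorber_amount(z0), 0)
  d1 <- gas_conditions(288.15, 1013.25, Z_km = 0.01)
  d2 <- gas_conditions(288.15, 1013.25, Z_km = 0.02)
  expect_equal(absorber_amount(d2), 2 * absorber_amount(d1), tolerance = 1e-12)
  # ideal-gas default air density at standard conditions
  expect_equal(gas_conditions(288.15, 1013.25)$rho_a, 1225, tolerance = 1e-3)
})

test_that("band model obeys its limits and temperature monotonicity", {
  Cp <- structure(list(wavelength = c(760.0, 760.6, 761.2),
                       value = c(-3, -2.47, -3.2), units = "transmittance"),
                  class = "spectrum")
  pp <- pierluisi_params(Cp)
  no_gas <- gas_conditions(288.15, 1013.25, Z_km = 0)
  expect_equal(pierluisi_transmittance(pp, no_gas)$value, rep(1, 3))
  # forced argument of 1: 10^C' U = 1 at standard conditions gives t = e^-1
  U_target <- 10^2.47
  cond <- gas_conditions(273.16, 1, rho_a = 1225, pressure_units = "atm",
                         Z_km = U_target / (0.7732e-4 * 209460 * 1225))
  expect_equal(absorber_amount(cond), U_target, tolerance = 1e-9)
  expect_equal(pierluisi_transmittance(pp, cond)$value[2L], exp(-1),
               tolerance = 1e-12)
  # warmer air absorbs less at every wavelength (m > 0)
  warm <- gas_conditions(313.15, 1, rho_a = 1225, pressure_units = "atm",
                         Z_km = cond$Z_km)
  expect_true(all(pierluisi_transmittance(pp, warm)$value >
                    pierluisi_transmittance(pp, cond)$value))
})

test_that("line-by-line engine is multiplicative in path only monochromatically", {
  lines <- default_line_list("O2A")
  g <- px_grid()
  geom0 <- path_geometry(sza = 0, vza = 0)
  t1 <- line_by_line_transmittance(g, lines,
                                   gas_conditions(288.15, 1013.25, Z_km = 0.010),
                                   geom0, "up")
  t2 <- line_by_line_transmittance(g, lines,
                                   gas_conditions(288.15, 1013.25, Z_km = 0.020),
                                   geom0, "up")
  expect_true(all(t1$value > 0 & t1$value <= 1))
  expect_lt(max(abs(t2$value - t1$value^2)), 1e-10)
  cfg <- sensor_config(1.0, 0.5, span = c(758, 769))
  conv_gap <- max(abs(convolve_and_sample(t2, cfg)$value -
                        convolve_and_sample(t1, cfg)$value^2))
  expect_gt(conv_gap, 1e-6)
  # zero-strength lines pass everything
  z <- lines; z$strength[] <- 0
  tz <- line_by_line_transmittance(g, z,
                                   gas_conditions(288.15, 1013.25, Z_km = 0.02),
                                   geom0, "up")
  expect_equal(tz$value, rep(1, length(g)))
  expect_error(line_by_line_transmittance(g, lines[0, ],
                                          gas_conditions(288.15, 1013.25, Z_km = 0.02),
                                          geom0, "up"),
               "empty")
  expect_error(line_by_line_transmittance(make_grid(755, 775, 0.02), lines,
                                          gas_conditions(288.15, 1013.25, Z_km = 0.02),
                                          geom0, "up"),
               "coarse")
})

test_that("band-depth calibration hits its target and is idempotent", {
  ll <- o2_line_list("O2A")
  cond_ref <- gas_conditions(288.15, 1013.25, Z_km = 0.010)
  c1 <- calibrate_band_depth(ll, 0.3, cond_ref)
  t <- convolve_and_sample(
    line_by_line_transmittance(px_grid(), c1, cond_ref,
                               path_geometry(sza = 0, vza = 0), "up"),
    proxsif:::bandmodel_sensor("O2A"))
  expect_equal(min(t$value), 0.3, tolerance = 1e-4)
  c2 <- calibrate_band_depth(c1, 0.3, cond_ref)
  expect_lt(max(abs(c2$strength / c1$strength - 1)), 1e-6)
  c_full <- calibrate_band_depth(ll, 1.0, cond_ref)
  expect_true(all(c_full$strength == 0))
  expect_error(calibrate_band_depth(ll, 0, cond_ref))
  # line list construction is deterministic given (band, n, seed)
  expect_identical(o2_line_list("O2A", seed = 0), o2_line_list("O2A", seed = 0))
  expect_false(identical(o2_line_list("O2A", seed = 1)$center_nm,
                         o2_line_list("O2A", seed = 0)$center_nm))
})

test_that("fitted band-model coefficients reproduce and extrapolate the engine", {
  lines <- default_line_list("O2A")
  cond <- gas_conditions(288.15, 1013.25, Z_km = 0.015)
  t_ref <- convolve_and_sample(
    line_by_line_transmittance(px_grid(), lines, cond,
                               path_geometry(sza = 0, vza = 0), "up"),
    proxsif:::bandmodel_sensor("O2A"))
  pp <- fit_pierluisi_coefficients(t_ref, cond)
  t_back <- pierluisi_transmittance(pp, cond)
  expect_equal(t_back$value, t_ref$value, tolerance = 1e-10)
  # no-absorption channels are flagged and clamped
  t_one <- spectrum(c(756, 760.6), c(1, 0.95), "transmittance")
  pp1 <- fit_pierluisi_coefficients(t_one, cond)
  expect_true(pp1$flagged[1L] && !pp1$flagged[2L])
  expect_equal(pp1$Cprime$value[1L], -12)
  # warming raises the band-minimum transmittance
  warm <- gas_conditions(288.15 + 40, 1013.25, Z_km = 0.015)
  expect_gt(min(pierluisi_transmittance(pp, warm)$value), min(t_ref$value))
  # band model vs engine stays within 2% in-band across T/p extremes
  inband <- t_ref$value < 0.999
  for (Tx in c(233, 313)) for (px in c(950, 1050)) {
    cx <- gas_conditions(Tx, px, Z_km = 0.015)
    a <- pierluisi_transmittance(pp, cx)$value[inband]
    b <- convolve_and_sample(
      line_by_line_transmittance(px_grid(), lines, cx,
                                 path_geometry(sza = 0, vza = 0), "up"),
      proxsif:::bandmodel_sensor("O2A"))$value[inband]
    expect_lt(max(abs(a / b - 1)), 0.02)
  }
})

test_that("barometric formula matches a hydrostatic ODE oracle", {
  # independent oracle: integrate dp/dz = -p g M0 / (R0 T) with deSolve
  k <- proxsif_constants()
  ode <- deSolve::ode(y = c(p = 1000), times = seq(0, 30, by = 1),
                      func = function(z, y, parms)
                        list(-y * k$g * k$M0 / (k$R0 * 283)),
                      parms = NULL, method = "ode45")
  p30 <- unname(ode[nrow(ode), "p"])
  expect_equal(pressure_at_height(1000, 283, 30), p30, tolerance = 1e-9)
  expect_equal(pressure_at_height(1000, 283, 30), 996.4, tolerance = 1e-4 * 996.4)
  expect_identical(pressure_at_height(1000, 283, 0), 1000)
  z <- seq(0, 100, by = 10)
  expect_true(all(diff(pressure_at_height(1000, 283, z)) < 0))
  # strict-paper mode reproduces the printed (positive-exponent) form
  expect_gt(pressure_at_height(1000, 283, 30, strict_paper = TRUE), 1000)
})

test_that("aerosol transmittance is smooth, monotone in path, and composes", {
  g <- px_grid()
  t0 <- aerosol_transmittance(g, 0, path_geometry(height_m = 20))
  expect_equal(t0$value, rep(1, length(g)))
  t3 <- aerosol_transmittance(g, 0.2, path_geometry(height_m = 3))
  t20 <- aerosol_transmittance(g, 0.2, path_geometry(height_m = 20))
  expect_true(all(t20$value < t3$value))
  w <- g >= 759 & g <= 768
  expect_lt(max(t20$value[w]) - min(t20$value[w]), 1e-4)
  sc <- px_scene(20)
  ones <- spectrum(g, rep(1, length(g)), "transmittance")
  expect_equal(total_transmittance(sc$t_up_O2, ones)$value, sc$t_up_O2$value)
  tot <- total_transmittance(sc$t_up_O2, t20)
  expect_true(all(tot$value <= pmin(sc$t_up_O2$value, t20$value) + 1e-15))
  # away from the line windows the total tends to the aerosol transmittance
  # (residual far Lorentz wings keep the agreement at the 1e-3 level)
  out <- g < 752 | g > 775
  expect_lt(max(abs(tot$value[out] - t20$value[out])), 1e-3)
})
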