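# Hertz-Sneddon / DMT fitting and stiffness maps.

test_that("Hertz cone fit is a clean roundtrip of the forward model", {
  tip <- tip_params()
  g <- make_force_curves(curve_grid_spec(grid_shape = c(1, 1), modulus_map = 4,
                                         model = "hertz_cone", noise_sd = 0,
                                         seed = 1))
  ft <- fit_hertz_cone(g$curves[[1L]], tip)
  expect_lt(abs(ft$Ea - 4) / 4, 0.01)
  expect_lt(abs(ft$contact_point), 2) # nm, zero-noise contact accuracy
  # linearity: doubling all forces doubles the fitted modulus
  cv2 <- g$curves[[1L]]
  cv2$force <- 2 * cv2$force
  expect_equal(fit_hertz_cone(cv2, tip)$Ea, 2 * ft$Ea, tolerance = 1e-6)
  # all-zero curve: no contact
  zero <- force_curve(cv2$separation, rep(0, length(cv2$force)), cv2$segment)
  expect_error(fit_hertz_cone(zero, tip), "no contact")
  # unit discipline: analytic curve in nm/nN comes back in MPa
  s <- seq(100, -100, length.out = 200)
  f <- (2 / pi) * tan(18 * pi / 180) * (5e-3 / 0.75) * pmax(-s, 0)^2
  an <- fit_hertz_cone(force_curve(c(s, rev(s)), c(f, rev(f)),
                                   rep(c("approach", "retract"), each = 200)),
                       tip)
  expect_lt(abs(an$Ea - 5) / 5, 0.01)
})

test_that("DMT fit recovers modulus and adhesion; nu conversion is explicit", {
  tip <- tip_params(poisson = 0.5)
  g <- make_force_curves(curve_grid_spec(grid_shape = c(1, 1), modulus_map = 6,
                                         model = "dmt_sphere",
                                         adhesion_force = 1, noise_sd = 0,
                                         seed = 1))
  ft <- fit_dmt_sphere(g$curves[[1L]], tip)
  expect_lt(abs(ft$Ea - 6) / 6, 0.01)
  expect_lt(abs(ft$F_adh - 1), 0.01)
  expect_equal(ft$Ea / ft$E_star, 0.75) # 1 - 0.5^2
  # zero-adhesion curve: adhesion estimate at the noise floor
  g0 <- make_force_curves(curve_grid_spec(grid_shape = c(1, 1),
                                          modulus_map = 6,
                                          model = "dmt_sphere",
                                          adhesion_force = 0, noise_sd = 0,
                                          seed = 2))
  expect_lt(fit_dmt_sphere(g0$curves[[1L]], tip)$F_adh, 1e-6)
  badtip <- tip_params(); badtip$radius <- NA_real_
  expect_error(fit_dmt_sphere(g$curves[[1L]], badtip), "radius")
})

test_that("fits stay unbiased under 5% multiplicative noise (200 replicates)", {
  tip <- tip_params()
  hz <- vapply(1:200, function(s) {
    g <- make_force_curves(curve_grid_spec(grid_shape = c(1, 1),
                                           modulus_map = 4,
                                           model = "hertz_cone",
                                           noise_sd = 0.05,
                                           noise_type = "multiplicative",
                                           seed = s))
    fit_hertz_cone(g$curves[[1L]], tip)$Ea
  }, 0)
  expect_lt(abs(mean(hz) / 4 - 1), 0.02)
  dm <- vapply(1:200, function(s) {
    g <- make_force_curves(curve_grid_spec(grid_shape = c(1, 1),
                                           modulus_map = 6,
                                           model = "dmt_sphere",
                                           adhesion_force = 1,
                                           noise_sd = 0.05,
                                           noise_type = "multiplicative",
                                           seed = s))
    fit_dmt_sphere(g$curves[[1L]], tip)$Ea
  }, 0)
  expect_lt(abs(mean(dm) / 6 - 1), 0.02)
})

test_that("stiffness maps recover homogeneous and two-phase samples", {
  tip <- tip_params()
  hom <- make_force_curves(curve_grid_spec(grid_shape = c(16, 16),
                                           modulus_map = 4,
                                           model = "hertz_cone",
                                           noise_sd = 0.02,
                                           noise_type = "multiplicative",
                                           seed = 5))
  sm <- build_stiffness_map(hom, tip, "hertz_cone")
  expect_equal(dim(sm$Ea), c(16L, 16L))
  expect_lt(abs(mean(sm$Ea, na.rm = TRUE) - 4) / 4, 0.03)
  # per-pixel scatter consistent with the injected noise (same order)
  expect_lt(stats::sd(sm$Ea, na.rm = TRUE) / 4, 0.05)
  # topography equals the injected height map (contact-point height)
  topo <- matrix(rep(seq(0, 30, length.out = 16), each = 16), 16, 16)
  g2 <- make_force_curves(curve_grid_spec(grid_shape = c(16, 16),
                                          modulus_map = 4,
                                          model = "hertz_cone", noise_sd = 0,
                                          height_map = topo, seed = 6))
  sm2 <- build_stiffness_map(g2, tip, "hertz_cone")
  expect_lt(max(abs(sm2$topography - topo)), 2)
})

test_that("the 128 x 128 scan convention is honored end to end", {
  tip <- tip_params()
  spec <- curve_grid_spec(modulus_map = 4, model = "hertz_cone",
                          noise_sd = 0, n_points = 40L, seed = 1)
  expect_identical(spec$grid_shape, c(128L, 128L)) # default digital resolution
  g <- make_force_curves(spec)
  expect_length(g$curves, 128L * 128L)
  sm <- build_stiffness_map(g, tip, "hertz_cone")
  expect_identical(dim(sm$Ea), c(128L, 128L))
})
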