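# Generators: jigsaw tissues, filament textures, force curves, severing
# series, dome meshes.

test_that("jigsaw tiling conserves area, is deterministic, and degenerates cleanly", {
  p <- jigsaw_params(n_cells = 5, domain_size = 100, lobe_amplitude = 3,
                     lobe_wavelength = 15, seed = 7)
  cx <- make_jigsaw_cells(p)
  expect_s3_class(cx, "cell_complex")
  # shoelace oracle: per-cell areas sum to the domain area
  areas <- vapply(seq_along(cx$cells),
                  function(i) abs(polygon_area(cell_ring(cx, i))), 0)
  expect_lt(abs(sum(areas) - 100^2) / 100^2, 0.001)
  # every ring is simple
  for (i in seq_along(cx$cells))
    expect_true(is_simple_polygon(cell_ring(cx, i)))
  # determinism
  cx2 <- make_jigsaw_cells(p)
  expect_identical(cx$vertices, cx2$vertices)
  expect_identical(cx$cells, cx2$cells)
  # landmarks point into the neck cell
  lm <- attr(cx, "landmarks")
  expect_gt(nrow(lm), 0)
  probe <- cbind(lm$x + 1.5 * lm$nx, lm$y + 1.5 * lm$ny)
  inside_neck <- vapply(seq_len(nrow(lm)), function(k)
    points_in_polygon(probe[k, 1L], probe[k, 2L],
                      cell_ring(cx, lm$neck_cell[k])), TRUE)
  expect_gt(mean(inside_neck), 0.9)
  # degenerate single-cell, no-lobe case: one convex polygon, full area
  c1 <- make_jigsaw_cells(jigsaw_params(n_cells = 1, lobe_amplitude = 0,
                                        seed = 1))
  expect_length(c1$cells, 1L)
  expect_equal(complex_area(c1), 100^2)
})

test_that("jigsaw edges are shared by at most two cells", {
  cx <- make_jigsaw_cells(jigsaw_params(n_cells = 6, seed = 2))
  # build_cell_complex would have errored on >2; assert the table structure
  expect_true(all(table(paste(pmin(cx$edges$v1, cx$edges$v2),
                              pmax(cx$edges$v1, cx$edges$v2))) == 1L))
  expect_true(all(is.na(cx$edges$cell_b[!cx$edges$shared])))
})

test_that("filament generator hits the prescribed nematic order", {
  # S = 1: every ground-truth angle equals the mean angle
  f1 <- make_filament_image(filament_image_spec(n_filaments = 50,
                                                order_parameter_S = 1,
                                                mean_angle = 30, seed = 1))
  expect_true(all(abs(f1$angles - 30) < 1e-9))
  # S = 0 and S = 0.5 at n = 2000: empirical circular moment within 0.05
  f0 <- make_filament_image(filament_image_spec(n_filaments = 2000,
                                                order_parameter_S = 0,
                                                seed = 2))
  expect_lt(order_parameter(f0$angles), 0.05)
  fh <- make_filament_image(filament_image_spec(n_filaments = 2000,
                                                order_parameter_S = 0.5,
                                                seed = 3))
  expect_lt(abs(order_parameter(fh$angles) - 0.5), 0.05)
  # seed determinism and S validation
  expect_identical(make_filament_image(filament_image_spec(seed = 9))$image,
                   make_filament_image(filament_image_spec(seed = 9))$image)
  expect_error(filament_image_spec(order_parameter_S = 1.2), "0, 1")
})

test_that("force-curve generator reproduces the forward models exactly", {
  tip <- tip_params(half_angle = 18, radius = 6, poisson = 0.5)
  # cone: F = (2/pi) tan(a) E/(1-nu^2) delta^2 at delta = 100 nm, E = 4 MPa
  expect_equal(contact_force(100, 4, tip, "hertz_cone"),
               (2 / pi) * tan(18 * pi / 180) * (4e-3 / 0.75) * 100^2,
               tolerance = 1e-12)
  g <- make_force_curves(curve_grid_spec(grid_shape = c(1, 1), modulus_map = 4,
                                         model = "hertz_cone", noise_sd = 0,
                                         seed = 1))
  cv <- g$curves[[1L]]
  app <- cv$segment == "approach"
  delta <- pmax(-cv$separation[app], 0)
  expect_equal(cv$force[app], contact_force(delta, 4, tip, "hertz_cone"),
               tolerance = 1e-12)
  # DMT: retract minimum equals -adhesion
  g2 <- make_force_curves(curve_grid_spec(grid_shape = c(1, 1), modulus_map = 6,
                                          model = "dmt_sphere",
                                          adhesion_force = 1, noise_sd = 0,
                                          seed = 1))
  expect_equal(min(g2$curves[[1L]]$force[g2$curves[[1L]]$segment == "retract"]),
               -1, tolerance = 1e-9)
  # two-phase map: contact stiffness differs by the model-predicted factor
  gs <- make_force_curves(curve_grid_spec(grid_shape = c(1, 2),
                                          modulus_map = matrix(c(2, 8), 1, 2),
                                          model = "hertz_cone", noise_sd = 0,
                                          seed = 1))
  f_at <- function(cv) max(cv$force)
  expect_equal(f_at(gs$curves[[2L]]) / f_at(gs$curves[[1L]]), 4,
               tolerance = 1e-9)
  expect_error(curve_grid_spec(modulus_map = -1), "positive")
})

test_that("severing series is Poisson with the stated intensity", {
  expect_equal(nrow(make_severing_series(
    severing_sim_spec(0, 100, 10, seed = 1))$events), 0L)
  # mean count over 500 replicates within 3 sigma of rate*area*duration = 100
  counts <- vapply(seq_len(500L), function(s)
    nrow(make_severing_series(severing_sim_spec(1e-3, 1e4, 10,
                                                seed = s))$events), 0L)
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 500))
  # determinism; positions and times inside their windows
  r1 <- make_severing_series(severing_sim_spec(1e-3, c(500, 800), 10, seed = 4))
  r2 <- make_severing_series(severing_sim_spec(1e-3, c(500, 800), 10, seed = 4))
  expect_identical(r1$events, r2$events)
  expect_true(all(r1$events$t >= 0 & r1$events$t <= 10))
})

test_that("guard-cell dome mesh has the stated apex and grows area with height", {
  expect_error(make_guard_cell_dome(radius = 10, mesh_h = 12), "smaller")
  flat <- make_guard_cell_dome(radius = 10, height = 0, mesh_h = 2)
  expect_equal(max(abs(flat$vertices[, 3L])), 0)
  dome <- make_guard_cell_dome(radius = 10, height = 5, mesh_h = 2)
  expect_equal(max(dome$vertices[, 3L]), 5, tolerance = 1e-9)
  # labeled as a guard-cell pair on a sheet
  expect_setequal(unique(dome$cell), c(1L, 2L, 3L))
  a_flat <- sum(mesh_areas(flat))
  areas <- vapply(c(2, 5, 8), function(h)
    sum(mesh_areas(make_guard_cell_dome(radius = 10, height = h, mesh_h = 2))),
    0)
  expect_true(all(diff(c(a_flat, areas)) > 0))
})
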