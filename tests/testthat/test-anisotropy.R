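# Texture tensor, nematic scores, multi-cell scoring.

test_that("score conventions and degenerate inputs", {
  # perfectly aligned orientation list: score 1 (v1) and 2 (v2)
  sc <- anisotropy_score(nematic_from_angles(rep(30, 100)))
  expect_equal(sc$score_v1, 1)
  expect_equal(sc$score_v2, 2)
  # equal orthogonal populations: eigenvalues tie, score 0
  sc0 <- anisotropy_score(nematic_from_angles(rep(c(0, 90), 50)))
  expect_equal(sc0$score_v1, 0, tolerance = 1e-12)
  # mixture: fraction f aligned at 0, rest isotropic -> score_v2 = 2f
  set.seed(5)
  ang <- c(rep(0, 1000), runif(1000, 0, 180))
  scm <- anisotropy_score(nematic_from_angles(ang))
  expect_lt(abs(scm$score_v2 - 1), 0.1) # 3 sigma Monte-Carlo band at n = 2000
  # score_v2 is exactly twice score_v1
  for (s in seq(0, 1, by = 0.25)) {
    f <- make_filament_image(filament_image_spec(n_filaments = 200,
                                                 order_parameter_S = s,
                                                 seed = 8))
    r <- anisotropy_score(texture_tensor(f$image))
    expect_identical(r$score_v2, 2 * r$score_v1)
  }
  # flat image: degenerate, scores 0
  flat <- texture_tensor(matrix(7, 64, 64))
  expect_true(flat$degenerate)
  expect_equal(anisotropy_score(flat)$score_v1, 0)
  expect_true(is.na(flat$mean_orientation))
})

test_that("orientation convention: stripes varying with y are 0-degree filaments", {
  img <- matrix(rep(100 * sin(seq(0, 16 * pi, length.out = 96)), 96), 96, 96)
  tt <- texture_tensor(img)
  expect_lt(min(tt$mean_orientation, 180 - tt$mean_orientation), 1)
  expect_gt(anisotropy_score(tt)$score_v1, 0.99)
})

test_that("scores are invariant to rotation, intensity scaling; orientation tracks rotation", {
  f <- make_filament_image(filament_image_spec(n_filaments = 400,
                                               order_parameter_S = 0.8,
                                               mean_angle = 20, seed = 13))
  roi <- roi_polygon(circle_polyline(90, 48) +
                       matrix(rep(c(128, 128), each = 48), 48, 2))
  t1 <- texture_tensor(f$image, roi)
  s1 <- anisotropy_score(t1)
  rot <- rotate_image(f$image, 37)
  t2 <- texture_tensor(rot, roi)
  s2 <- anisotropy_score(t2)
  expect_lt(abs(s2$score_v1 - s1$score_v1) / s1$score_v1, 0.02)
  expect_lt(axial_angle_diff(t2$mean_orientation, t1$mean_orientation + 37), 3)
  # intensity scaling leaves tensor and scores unchanged
  t3 <- texture_tensor(f$image * 3.7, roi)
  expect_equal(t3$tensor, t1$tensor, tolerance = 1e-12)
})

test_that("mean image score is nondecreasing in the ground-truth order parameter", {
  score_at <- function(S) {
    mean(vapply(1:3, function(k) {
      f <- make_filament_image(filament_image_spec(n_filaments = 2000,
                                                   order_parameter_S = S,
                                                   seed = 100 + k))
      anisotropy_score(texture_tensor(f$image))$score_v1
    }, 0))
  }
  sc <- vapply(c(0, 0.25, 0.5, 0.75, 1), score_at, 0)
  expect_true(all(diff(sc) > 0))
  expect_lt(sc[1L], 0.05) # S = 0 image
  expect_gt(sc[5L], 0.95) # S = 1 image
})

test_that("score_cells produces a tidy per-cell table with stable ordering", {
  f <- make_filament_image(filament_image_spec(seed = 3))
  r1 <- roi_polygon(cbind(c(20, 120, 120, 20), c(20, 20, 120, 120)), "a")
  r2 <- roi_polygon(cbind(c(130, 240, 240, 130), c(130, 130, 240, 240)), "b")
  tab1 <- score_cells(f$image, list(r1))
  expect_equal(nrow(tab1), 1L)
  tab <- score_cells(f$image, list(r2, r1))
  tab_swapped <- score_cells(f$image, list(r1, r2))
  expect_equal(tab, tab_swapped)
  # neck/lobe style contrast: higher ground-truth order scores higher
  hi <- make_filament_image(filament_image_spec(order_parameter_S = 0.8,
                                                n_filaments = 600, seed = 4))
  lo <- make_filament_image(filament_image_spec(order_parameter_S = 0.4,
                                                n_filaments = 600, seed = 4))
  th <- score_cells(list(hi$image, lo$image), list(r1, r2), timepoints = 1:2)
  m <- tapply(th$score_v1, th$time, mean)
  expect_gt(m[["1"]], m[["2"]])
  # a ROI that fails at one timepoint yields an NA row, not an error
  tiny <- roi_polygon(cbind(c(1, 4, 4, 1), c(1, 1, 4, 4)), "tiny")
  suppressMessages(bad <- score_cells(f$image, list(r1, tiny)))
  expect_true(is.na(bad$score_v1[bad$cell == "tiny"]))
  expect_false(is.na(bad$score_v1[bad$cell == "a"]))
})

test_that("wall-band exclusion erodes the ROI inward", {
  f <- make_filament_image(filament_image_spec(seed = 6))
  ring <- cbind(c(50, 200, 200, 50), c(50, 50, 200, 200))
  full <- texture_tensor(f$image, roi_polygon(ring))
  erod <- texture_tensor(f$image, roi_polygon(ring, exclude_wall_band = TRUE,
                                              band_px = 5))
  expect_lt(erod$n_pixels, full$n_pixels)
})
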