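# Cell complexes, constrained meshing, beams, height-map projection.

test_that("cell complex adjacency matches brute-force shared-edge search", {
  one <- build_cell_complex(list(unit_square_ring()))
  expect_length(one$cells, 1L)
  expect_equal(sum(one$edges$shared), 0L)
  expect_length(one$outer_boundary, 4L)

  two <- build_cell_complex(list(unit_square_ring(),
                                 unit_square_ring(1, c(1, 0))))
  expect_equal(sum(two$edges$shared), 1L)
  expect_equal(nrow(two$adjacency), 1L)
  expect_length(two$outer_boundary, 6L)

  grid9 <- build_cell_complex(lapply(0:8, function(k)
    unit_square_ring(1, c(k %% 3, k %/% 3))))
  # brute force: cells sharing a full edge
  brute <- 0L
  for (i in 1:8) for (j in (i + 1):9) {
    ri <- unit_square_ring(1, c((i - 1) %% 3, (i - 1) %/% 3))
    rj <- unit_square_ring(1, c((j - 1) %% 3, (j - 1) %/% 3))
    ei <- lapply(1:4, function(k) rbind(ri[k, ], ri[k %% 4 + 1, ]))
    ej <- lapply(1:4, function(k) rbind(rj[k, ], rj[k %% 4 + 1, ]))
    hit <- any(vapply(ei, function(a) any(vapply(ej, function(b)
      isTRUE(all.equal(a, b[2:1, ])) || isTRUE(all.equal(a, b)), TRUE)), TRUE))
    if (hit) brute <- brute + 1L
  }
  expect_equal(nrow(grid9$adjacency), brute)
  ctr <- 5L # center square
  expect_equal(sum(grid9$adjacency$cell_a == ctr | grid9$adjacency$cell_b == ctr),
               4L)
})

test_that("cell complex rejects malformed input", {
  expect_error(build_cell_complex(list(unit_square_ring(),
                                       unit_square_ring(1, c(0.5, 0)))),
               "overlap")
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(build_cell_complex(list(bowtie)), "simple")
})

test_that("constrained mesh conserves area and respects boundaries", {
  sq <- build_cell_complex(list(unit_square_ring(10)))
  m <- mesh_surface(sq, target_h = 1)
  ed <- rbind(m$triangles[, 1:2], m$triangles[, 2:3], m$triangles[, c(3, 1)])
  el <- sqrt(rowSums((m$vertices[ed[, 1L], ] - m$vertices[ed[, 2L], ])^2))
  expect_lt(max(el), 1.5 * 1)
  expect_lt(abs(sum(mesh_areas(m)) - 100) / 100, 0.005)
  # boundary vertices lie exactly on the square outline
  bv <- m$vertices[m$z_fixed, 1:2]
  on_edge <- abs(bv[, 1L]) < 1e-9 | abs(bv[, 1L] - 10) < 1e-9 |
    abs(bv[, 2L]) < 1e-9 | abs(bv[, 2L] - 10) < 1e-9
  expect_true(all(on_edge))
  # meshing is deterministic
  m2 <- mesh_surface(sq, target_h = 1)
  expect_identical(m$vertices, m2$vertices)
  expect_identical(m$triangles, m2$triangles)
})

test_that("jigsaw mesh labels partition elements and conserve per-cell area", {
  fx <- fx_jigsaw_template()
  m <- fx$mesh; cx <- fx$complex
  expect_false(any(is.na(m$cell)))
  areas <- tapply(mesh_areas(m), m$cell, sum)
  ref <- vapply(seq_along(cx$cells),
                function(i) abs(polygon_area(cell_ring(cx, i))), 0)
  expect_equal(as.numeric(areas), ref, tolerance = 0.005)
  # interior walls appear as mesh edges: every boundary segment is an edge
  tk <- paste(pmin(c(m$triangles[, 1L], m$triangles[, 2L], m$triangles[, 3L]),
                   c(m$triangles[, 2L], m$triangles[, 3L], m$triangles[, 1L])),
              pmax(c(m$triangles[, 1L], m$triangles[, 2L], m$triangles[, 3L]),
                   c(m$triangles[, 2L], m$triangles[, 3L], m$triangles[, 1L])))
  segs <- m$boundary_segments
  expect_true(all(paste(pmin(segs$v1, segs$v2), pmax(segs$v1, segs$v2)) %in% tk))
})

test_that("anticlinal beams follow the published rule", {
  fx <- fx_jigsaw_template()
  mat <- material_params() # defaults: E 40, wall 1 um, fraction 1/5
  m <- add_anticlinal_beams(fx$mesh, mat)
  expect_equal(nrow(m$beams), nrow(m$boundary_segments))
  expect_true(all(m$beams$thickness == 0.2)) # 1/5 of the 1 um wall
  expect_true(all(m$beams$modulus == 40))    # matrix modulus
  # beams lie exactly on cell-boundary vertices (z-fixed set)
  expect_true(all(m$z_fixed[c(m$beams$v1, m$beams$v2)]))
})

test_that("height-map projection interpolates bilinearly", {
  sq <- build_cell_complex(list(unit_square_ring(10)))
  m <- mesh_surface(sq, target_h = 1.5)
  gx <- seq(-1, 11, by = 0.5); gy <- seq(-1, 11, by = 0.5)
  zero <- list(x = gx, y = gy, z = matrix(0, length(gx), length(gy)))
  expect_equal(project_to_heightmap(m, zero)$vertices, m$vertices)
  cst <- list(x = gx, y = gy, z = matrix(3.5, length(gx), length(gy)))
  expect_equal(project_to_heightmap(m, cst)$vertices[, 3L],
               rep(3.5, nrow(m$vertices)))
  # analytic Gaussian bump: pointwise evaluation oracle
  f <- function(x, y) 4 * exp(-((x - 5)^2 + (y - 5)^2) / 8)
  bump <- list(x = gx, y = gy, z = outer(gx, gy, f))
  pm <- project_to_heightmap(m, bump)
  direct <- f(m$vertices[, 1L], m$vertices[, 2L])
  # bilinear error bound ~ h_grid^2 * |f''| / 8
  expect_lt(max(abs(pm$vertices[, 3L] - direct)), 0.5^2 * 2 / 8 + 1e-6)
  off <- m; off$vertices[1L, 1L] <- -50
  expect_error(project_to_heightmap(off, bump), "outside")
})
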