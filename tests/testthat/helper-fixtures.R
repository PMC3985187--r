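# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

unit_square_ring <- function(side = 1, origin = c(0, 0)) {
  cbind(origin[1L] + c(0, side, side, 0), origin[2L] + c(0, 0, side, side))
}

# small two-cell template mesh with beams (fast mechanics fixture)
fx_two_cell_mesh <- function() fixture("two_cell_mesh", function() {
  cxx <- build_cell_complex(list(unit_square_ring(20),
                                 unit_square_ring(20, c(20, 0))))
  mat <- material_params(fiber_ratio = 1)
  m <- mesh_surface(cxx, target_h = 4)
  add_anticlinal_beams(m, mat)
})

# default 5-cell jigsaw template solved under default isotropic loads
fx_jigsaw_template <- function() fixture("jigsaw_template", function() {
  cx <- make_jigsaw_cells(jigsaw_params(n_cells = 5, domain_size = 100,
                                        seed = 7))
  mat <- material_params(fiber_ratio = 1)
  mesh <- add_anticlinal_beams(mesh_surface(cx, target_h = 2.5), mat)
  d <- solve_equilibrium(mesh, mat)
  list(complex = cx, mesh = mesh, material = mat, disp = d,
       stress = principal_stress(d, mesh, mat))
})

# synthetic stress field on a ring of elements around the origin with a
# prescribed in-plane direction rule (for the circumferential score)
fake_ring_stress <- function(n = 400, r = 10, dir = c("tangent", "radial",
                                                      "random"), seed = 1) {
  dir <- match.arg(dir)
  set.seed(seed)
  th <- runif(n, 0, 2 * pi)
  rr <- r + runif(n, 0.5, 5)
  cen <- cbind(rr * cos(th), rr * sin(th), 0)
  ang <- switch(dir,
                tangent = th + pi / 2,
                radial = th,
                random = runif(n, 0, pi))
  d1 <- cbind(cos(ang), sin(ang), 0)
  structure(list(sigma1 = rep(1, n), sigma2 = rep(0.5, n), dir1 = d1,
                 dir2 = cbind(-sin(ang), cos(ang), 0),
                 degenerate = rep(FALSE, n), area = rep(1, n),
                 centroid = cen, cell = rep(1L, n)),
            class = "stress_field")
}

circle_polyline <- function(r = 10, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(r * cos(th), r * sin(th))
}

# bilinear rotation of an image about its center (values outside -> 0)
rotate_image <- function(img, deg) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- -deg * pi / 180
  out <- matrix(0, h, w)
  xs <- rep(seq_len(w), each = h) - cx
  ys <- rep(seq_len(h), w) - cy
  sx <- cx + xs * cos(th) - ys * sin(th)
  sy <- cy + xs * sin(th) + ys * cos(th)
  ix <- floor(sx); iy <- floor(sy)
  ok <- ix >= 1 & ix < w & iy >= 1 & iy < h
  fx <- sx - ix; fy <- sy - iy
  v <- numeric(length(xs))
  id <- function(i, j) (j - 1L) * h + i
  v[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * img[id(iy[ok], ix[ok])] +
    fx[ok] * (1 - fy[ok]) * img[id(iy[ok], ix[ok] + 1L)] +
    (1 - fx[ok]) * fy[ok] * img[id(iy[ok] + 1L, ix[ok])] +
    fx[ok] * fy[ok] * img[id(iy[ok] + 1L, ix[ok] + 1L)]
  matrix(v, h, w)
}

axial_angle_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
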