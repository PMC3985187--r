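# Analytic benchmark meshes: icosphere (Laplace-law oracle), capsule
# (hoop/axial ratio oracle), dome-on-sheet (elevated stoma), closed
# spherical cap (plate compression).

#' Triangulated sphere (subdivided icosahedron)
#'
#' @param radius sphere radius (um).
#' @param subdiv subdivision level; 0 is the bare icosahedron, each level
#'   quadruples the triangle count (20 * 4^subdiv).
#' @return a closed [surface_mesh()] with outward-oriented triangles.
#' @export
make_sphere_mesh <- function(radius = 20, subdiv = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdiv)) {
    mid <- new.env()
    nf <- matrix(0L, 4L * nrow(f), 3L)
    getmid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid[[key]])) return(mid[[key]])
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid[[key]] <- nrow(v)
      nrow(v)
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c3 <- f[i, 3L]
      ab <- getmid(a, b); bc <- getmid(b, c3); ca <- getmid(c3, a)
      nf[4L * i - 3L, ] <- c(a, ab, ca)
      nf[4L * i - 2L, ] <- c(b, bc, ab)
      nf[4L * i - 1L, ] <- c(c3, ca, bc)
      nf[4L * i, ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  surface_mesh(v * radius, f, closed = TRUE)
}

#' Capsule (cylinder with hemispherical caps), axis along z
#'
#' The benchmark for the pressurized-cylinder stress state: away from the
#' caps the hoop:axial membrane stress ratio is 2.
#'
#' @param radius cylinder radius (um).
#' @param length cylinder (straight section) length (um).
#' @param mesh_h target element size (um).
#' @return a closed [surface_mesh()]. Elements of the straight section carry
#'   cell label 1, caps label 2.
#' @export
make_capsule_mesh <- function(radius = 10, length = 60, mesh_h = 2) {
  stopifnot(radius > 0, length >= 0, mesh_h < radius)
  nv <- max(12L, ceiling(2 * pi * radius / mesh_h))
  # meridian profile from south pole to north pole: (r(s), z(s))
  ncap <- max(4L, ceiling((pi / 2) * radius / mesh_h))
  ncyl <- max(2L, ceiling(length / mesh_h))
  a_s <- seq(-pi / 2, 0, length.out = ncap + 1L)
  prof <- cbind(radius * cos(a_s), radius * sin(a_s))
  prof <- rbind(prof, cbind(radius, seq(0, length, length.out = ncyl + 1L)[-1L]))
  a_n <- seq(0, pi / 2, length.out = ncap + 1L)[-1L]
  prof <- rbind(prof, cbind(radius * cos(a_n), length + radius * sin(a_n)))
  m <- nrow(prof)
  th <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  # interior rings (exclude the two poles)
  rings <- prof[2:(m - 1L), , drop = FALSE]
  nr <- nrow(rings)
  verts <- cbind(rep(rings[, 1L], each = nv) * cos(th),
                 rep(rings[, 1L], each = nv) * sin(th),
                 rep(rings[, 2L], each = nv))
  south <- nrow(verts) + 1L; north <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, -radius), c(0, 0, length + radius))
  vid <- function(i, j) (i - 1L) * nv + ((j - 1L) %% nv) + 1L
  tri <- NULL
  for (i in seq_len(nr - 1L))
    for (j in seq_len(nv)) {
      tri <- rbind(tri,
                   c(vid(i, j), vid(i, j + 1L), vid(i + 1L, j)),
                   c(vid(i, j + 1L), vid(i + 1L, j + 1L), vid(i + 1L, j)))
    }
  for (j in seq_len(nv)) {
    tri <- rbind(tri, c(south, vid(1L, j + 1L), vid(1L, j)),
                 c(north, vid(nr, j), vid(nr, j + 1L)))
  }
  mesh <- surface_mesh(verts, tri, closed = TRUE)
  # orient outward (positive enclosed volume)
  if (mesh_enclosed_volume(mesh) < 0)
    mesh$triangles[, c(2L, 3L)] <- mesh$triangles[, c(3L, 2L)]
  zc <- (verts[mesh$triangles[, 1L], 3L] + verts[mesh$triangles[, 2L], 3L] +
           verts[mesh$triangles[, 3L], 3L]) / 3
  mesh$cell <- ifelse(zc > 0 & zc < length, 1L, 2L)
  mesh
}

#' Dome on a flat sheet: the elevated-stoma template
#'
#' A square sheet with a centered Gaussian bump
#' `z = height * exp(-r^2 / (2 sigma^2))`, `sigma = radius/2`, so the bump is
#' essentially contained within `r < radius` and the apex sits exactly at
#' `height`. Elements under the bump footprint are labeled as a guard-cell
#' pair (labels 2 and 3, split at x = 0); the sheet is cell 1. Only the
#' outer sheet boundary is flagged for constraints.
#'
#' @param radius bump footprint radius (um).
#' @param height apex height (um, >= 0); 0 gives a flat sheet.
#' @param mesh_h grid spacing (um, < radius).
#' @param span sheet side length (um; default 6 * radius).
#' @return an open [surface_mesh()].
#' @export
make_guard_cell_dome <- function(radius = 10, height = 5, mesh_h = 1,
                                 span = 6 * radius) {
  stopifnot(height >= 0)
  if (mesh_h >= radius) stop("mesh_h must be smaller than radius")
  n2 <- ceiling(span / 2 / mesh_h)
  g <- seq(-n2, n2) * mesh_h          # odd count; includes 0
  nx <- length(g)
  verts <- cbind(rep(g, nx), rep(g, each = nx))
  r2 <- verts[, 1L]^2 + verts[, 2L]^2
  sig <- radius / 2
  z <- height * exp(-r2 / (2 * sig^2))
  vid <- function(i, j) (j - 1L) * nx + i
  tri <- matrix(0L, 2L * (nx - 1L)^2, 3L)
  k <- 0L
  for (j in seq_len(nx - 1L))
    for (i in seq_len(nx - 1L)) {
      # alternate the quad diagonal for isotropy
      if ((i + j) %% 2L == 0L) {
        tri[k + 1L, ] <- c(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L))
        tri[k + 2L, ] <- c(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
      } else {
        tri[k + 1L, ] <- c(vid(i, j), vid(i + 1L, j), vid(i, j + 1L))
        tri[k + 2L, ] <- c(vid(i + 1L, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
      }
      k <- k + 2L
    }
  cen <- (verts[tri[, 1L], , drop = FALSE] + verts[tri[, 2L], , drop = FALSE] +
            verts[tri[, 3L], , drop = FALSE]) / 3
  rc <- sqrt(cen[, 1L]^2 + cen[, 2L]^2)
  cell <- ifelse(rc < radius, ifelse(cen[, 1L] < 0, 2L, 3L), 1L)
  onb <- abs(verts[, 1L]) >= max(g) - 1e-9 | abs(verts[, 2L]) >= max(g) - 1e-9
  surface_mesh(cbind(verts, z), tri, cell = cell,
               z_fixed = onb, outer = onb, closed = FALSE)
}

#' Closed spherical cap standing on a rigid base
#'
#' A spherical cap of the given base radius and apex height, closed by a flat
#' base disk so the enclosed volume is defined; base vertices are marked
#' `z_fixed` and `outer` (the solver fully clamps them). Used for the
#' plate-compression experiments.
#'
#' @param radius base circle radius (um).
#' @param height apex height (um, 0 < height).
#' @param mesh_h target element size (um).
#' @return a closed [surface_mesh()]; cap elements are cell 1, base disk
#'   cell 2.
#' @export
make_cap_mesh <- function(radius = 10, height = 8, mesh_h = 1.2) {
  stopifnot(radius > 0, height > 0, mesh_h < radius)
  # sphere through base circle (radius a at z=0) with apex at height h:
  # R = (a^2 + h^2) / (2h), center z0 = h - R
  R <- (radius^2 + height^2) / (2 * height)
  z0 <- height - R
  th_max <- acos((0 - z0) / R) # polar angle of base ring (from +z)
  nrad <- max(4L, ceiling(th_max * R / mesh_h))
  ths <- seq(0, th_max, length.out = nrad + 1L)[-1L]
  nv <- max(12L, ceiling(2 * pi * radius / mesh_h))
  th <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  verts <- matrix(c(0, 0, height), 1L, 3L) # apex
  for (i in seq_along(ths)) {
    r <- R * sin(ths[i])
    verts <- rbind(verts, cbind(r * cos(th), r * sin(th), z0 + R * cos(ths[i])))
  }
  vid <- function(i, j) 1L + (i - 1L) * nv + ((j - 1L) %% nv) + 1L
  tri <- NULL
  for (j in seq_len(nv)) # apex fan
    tri <- rbind(tri, c(1L, vid(1L, j), vid(1L, j + 1L)))
  for (i in seq_len(length(ths) - 1L))
    for (j in seq_len(nv))
      tri <- rbind(tri,
                   c(vid(i, j), vid(i + 1L, j), vid(i, j + 1L)),
                   c(vid(i, j + 1L), vid(i + 1L, j), vid(i + 1L, j + 1L)))
  # base disk: center + last ring
  base_center <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, 0))
  cap_tri_n <- nrow(tri)
  nL <- nv
  sL <- 1L + (length(ths) - 1L) * nv + 1L
  for (j in seq_len(nL))
    tri <- rbind(tri, c(base_center, sL + (j %% nL), sL + j - 1L))
  mesh <- surface_mesh(verts, tri,
                       cell = c(rep(1L, cap_tri_n), rep(2L, nL)),
                       closed = TRUE)
  if (mesh_enclosed_volume(mesh) < 0)
    mesh$triangles[, c(2L, 3L)] <- mesh$triangles[, c(3L, 2L)]
  base_ring <- c(base_center, sL:(sL + nL - 1L))
  mesh$z_fixed[base_ring] <- TRUE
  mesh$outer[base_ring] <- TRUE
  mesh
}

#' Enclosed volume of a closed surface mesh
#' @param mesh a closed `surface_mesh`.
#' @param X optional coordinates overriding `mesh$vertices`.
#' @return signed volume (positive for outward orientation).
#' @export
mesh_enclosed_volume <- function(mesh, X = NULL) {
  if (is.null(X)) X <- mesh$vertices
  t1 <- mesh$triangles[, 1L]; t2 <- mesh$triangles[, 2L]; t3 <- mesh$triangles[, 3L]
  p1 <- X[t1, , drop = FALSE]; p2 <- X[t2, , drop = FALSE]; p3 <- X[t3, , drop = FALSE]
  sum(p1[, 1L] * (p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L]) +
        p1[, 2L] * (p2[, 3L] * p3[, 1L] - p2[, 1L] * p3[, 3L]) +
        p1[, 3L] * (p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L])) / 6
}
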