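# Simulation-ready shell meshes: constrained triangulation of a cell
# complex, boundary beam bookkeeping, optional projection onto a measured
# height field. Meshes start flat (z = 0); the solver inflates them.

#' Surface mesh constructor
#'
#' Low-level constructor used by the meshers; most users call
#' [mesh_surface()] or a primitive generator.
#'
#' @param vertices V x 3 coordinates (um).
#' @param triangles T x 3 vertex indices (1-based, counter-clockwise seen
#'   from +z / outside).
#' @param cell per-element cell label (integer).
#' @param thickness per-element wall thickness (um); recycled.
#' @param fiber T x 3 fiber directions (rows of zeros = isotropic element).
#' @param z_fixed,outer per-vertex constraint flags.
#' @param boundary_segments data.frame of cell-boundary mesh edges
#'   (`v1`, `v2`, `cell_a`, `cell_b`, `shared`).
#' @param closed is the surface closed (watertight)? Decides which
#'   pressure-volume potential the solver uses.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, cell = 1L, thickness = 1,
                         fiber = NULL, z_fixed = NULL, outer = NULL,
                         boundary_segments = NULL, closed = FALSE) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  stopifnot(ncol(vertices) == 3L, ncol(triangles) == 3L)
  T <- nrow(triangles)
  m <- list(
    vertices = vertices, triangles = triangles,
    cell = rep_len(as.integer(cell), T),
    thickness = rep_len(as.numeric(thickness), T),
    fiber = if (is.null(fiber)) matrix(0, T, 3L) else as.matrix(fiber),
    z_fixed = if (is.null(z_fixed)) logical(nrow(vertices)) else z_fixed,
    outer = if (is.null(outer)) logical(nrow(vertices)) else outer,
    boundary_segments = boundary_segments,
    beams = NULL, closed = closed)
  class(m) <- "surface_mesh"
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$triangles),
      "triangles,", length(unique(x$cell)), "cells,",
      if (is.null(x$beams)) 0L else nrow(x$beams), "beams,",
      if (x$closed) "closed" else "open", "\n")
  invisible(x)
}

#' Element areas of a surface mesh (deformed coordinates optional)
#' @param mesh a `surface_mesh`.
#' @param X optional V x 3 coordinates overriding `mesh$vertices`.
#' @return numeric vector of triangle areas.
#' @export
mesh_areas <- function(mesh, X = NULL) {
  if (is.null(X)) X <- mesh$vertices
  t1 <- mesh$triangles[, 1L]; t2 <- mesh$triangles[, 2L]; t3 <- mesh$triangles[, 3L]
  u <- X[t2, , drop = FALSE] - X[t1, , drop = FALSE]
  v <- X[t3, , drop = FALSE] - X[t1, , drop = FALSE]
  cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

mesh_unique_edges <- function(triangles) {
  e1 <- c(triangles[, 1L], triangles[, 2L], triangles[, 3L])
  e2 <- c(triangles[, 2L], triangles[, 3L], triangles[, 1L])
  k <- paste(pmin(e1, e2), pmax(e1, e2))
  keep <- !duplicated(k)
  cbind(pmin(e1, e2)[keep], pmax(e1, e2)[keep])
}

#' Mesh a cell complex with triangles constrained to the cell boundaries
#'
#' Cell-boundary polylines are resampled at spacing at most `target_h` (each
#' shared wall once, so neighboring cells keep geometrically identical
#' boundary vertices), interiors are filled with a jittered hexagonal point
#' lattice, and each cell is triangulated by Delaunay insertion. Boundary
#' conformity is repaired by subdividing any wall segment that fails to
#' appear as a mesh edge (at most 4 rounds). Interior vertices are relaxed by
#' two Laplacian smoothing passes with a fold-over guard. The result is flat
#' (z = 0).
#'
#' @param complex a [build_cell_complex()] object.
#' @param target_h target element edge length (um).
#' @param thickness wall thickness carried per element (um).
#' @param smooth_iter Laplacian smoothing passes.
#' @return a [surface_mesh()] with per-element cell labels, per-vertex
#'   `z_fixed` (on any cell boundary) and `outer` flags, and
#'   `boundary_segments` ready for [add_anticlinal_beams()].
#' @export
mesh_surface <- function(complex, target_h, thickness = 1, smooth_iter = 2L) {
  stopifnot(inherits(complex, "cell_complex"), target_h > 0)
  edges <- complex$edges
  V2 <- complex$vertices
  elen <- sqrt((V2[edges$v2, 1L] - V2[edges$v1, 1L])^2 +
                 (V2[edges$v2, 2L] - V2[edges$v1, 2L])^2)
  min_cell_diam <- sqrt(min(vapply(seq_along(complex$cells), function(i)
    abs(polygon_area(cell_ring(complex, i))), 0)))
  if (target_h > 0.5 * min_cell_diam)
    warning("target_h larger than the smallest cell feature; refining locally")
  nseg <- pmax(1L, ceiling(elen / target_h))

  for (round in seq_len(4L)) {
    edge_pts <- lapply(seq_len(nrow(edges)), function(k) {
      a <- V2[edges$v1[k], ]; b <- V2[edges$v2[k], ]
      s <- seq(0, 1, length.out = nseg[k] + 1L)
      p <- cbind(a[1L] + s * (b[1L] - a[1L]), a[2L] + s * (b[2L] - a[2L]))
      p[1L, ] <- a; p[nseg[k] + 1L, ] <- b # endpoints bit-exact
      p
    })
    res <- try(mesh_cells_once(complex, edge_pts, target_h), silent = TRUE)
    if (!inherits(res, "try-error") && is.null(res$missing)) break
    if (inherits(res, "try-error")) stop(res)
    nseg[res$missing] <- nseg[res$missing] * 2L
    if (round == 4L) stop("could not recover all boundary segments; reduce target_h")
  }

  mesh <- res$mesh
  mesh$thickness <- rep_len(thickness, nrow(mesh$triangles))
  if (smooth_iter > 0L) mesh <- smooth_mesh(mesh, smooth_iter)
  mesh$complex <- complex
  mesh
}

mesh_cells_once <- function(complex, edge_pts, h) {
  edges <- complex$edges
  ekey <- paste(pmin(edges$v1, edges$v2), pmax(edges$v1, edges$v2))
  n_cells <- length(complex$cells)
  all_pts <- NULL; all_tri <- NULL; all_cell <- integer(0)
  key_of <- function(p) {
    x <- round(p[, 1L], 9L); y <- round(p[, 2L], 9L)
    x[x == 0] <- 0; y[y == 0] <- 0 # normalize negative zero
    paste(sprintf("%.9f", x), sprintf("%.9f", y))
  }
  seg_rows <- list()
  for (ci in seq_len(n_cells)) {
    ids <- complex$cells[[ci]]
    n <- length(ids)
    Bc <- NULL; seg_edge <- integer(0)
    for (i in seq_len(n)) {
      u <- ids[i]; v <- ids[if (i == n) 1L else i + 1L]
      k <- match(paste(min(u, v), max(u, v)), ekey)
      pl <- edge_pts[[k]]
      if (edges$v1[k] != u) pl <- pl[rev(seq_len(nrow(pl))), , drop = FALSE]
      Bc <- rbind(Bc, pl[-nrow(pl), , drop = FALSE])
      seg_edge <- c(seg_edge, rep.int(k, nrow(pl) - 1L))
    }
    nb <- nrow(Bc)
    ring <- Bc
    # hexagonal interior lattice, clear of the boundary
    bb <- apply(ring, 2L, range)
    dy <- h * sqrt(3) / 2
    ys <- seq(bb[1L, 2L] + 0.5 * dy, bb[2L, 2L] - 0.25 * dy, by = dy)
    cand <- NULL
    for (j in seq_along(ys)) {
      x0 <- bb[1L, 1L] + if (j %% 2L) 0.5 * h else h
      xs <- seq(x0, bb[2L, 1L] - 0.25 * h, by = h)
      if (length(xs)) cand <- rbind(cand, cbind(xs, ys[j]))
    }
    interior <- NULL
    if (!is.null(cand) && nrow(cand)) {
      inside <- points_in_polygon(cand[, 1L], cand[, 2L], ring)
      cand <- cand[inside, , drop = FALSE]
      if (nrow(cand)) {
        dmin <- rep(Inf, nrow(cand))
        for (i in seq_len(nb)) {
          a <- Bc[i, ]; b <- Bc[if (i == nb) 1L else i + 1L, ]
          dmin <- pmin(dmin, dist_point_segment(cand[, 1L], cand[, 2L], a, b))
        }
        cand <- cand[dmin >= 0.72 * h, , drop = FALSE]
        if (nrow(cand)) {
          jx <- sin(seq_len(nrow(cand)) * 12.9898 + ci) * 43758.5453
          jy <- sin(seq_len(nrow(cand)) * 78.233 + ci) * 12345.6789
          interior <- cand + 0.02 * h * cbind(jx - floor(jx) - 0.5,
                                              jy - floor(jy) - 0.5)
        }
      }
    }
    pts <- rbind(Bc, interior)
    tri <- delaunay_triangulate(pts)
    cen <- (pts[tri[, 1L], , drop = FALSE] + pts[tri[, 2L], , drop = FALSE] +
              pts[tri[, 3L], , drop = FALSE]) / 3
    tri <- tri[points_in_polygon(cen[, 1L], cen[, 2L], ring), , drop = FALSE]
    # boundary conformity
    tk <- paste(pmin(c(tri[, 1L], tri[, 2L], tri[, 3L]),
                     c(tri[, 2L], tri[, 3L], tri[, 1L])),
                pmax(c(tri[, 1L], tri[, 2L], tri[, 3L]),
                     c(tri[, 2L], tri[, 3L], tri[, 1L])))
    bi <- seq_len(nb); bj <- c(bi[-1L], 1L)
    bk <- paste(pmin(bi, bj), pmax(bi, bj))
    miss <- !(bk %in% tk)
    if (any(miss)) return(list(missing = unique(seg_edge[miss])))
    off <- if (is.null(all_pts)) 0L else nrow(all_pts)
    all_pts <- rbind(all_pts, pts)
    all_tri <- rbind(all_tri, tri + off)
    all_cell <- c(all_cell, rep.int(ci, nrow(tri)))
    seg_rows[[ci]] <- data.frame(
      v1 = off + bi, v2 = off + bj,
      cell_a = edges$cell_a[seg_edge], cell_b = edges$cell_b[seg_edge],
      shared = edges$shared[seg_edge], boundary = TRUE)
  }
  # merge duplicate (shared-boundary) vertices
  keys <- key_of(all_pts)
  uk <- !duplicated(keys)
  map <- match(keys, keys[uk])
  verts <- all_pts[uk, , drop = FALSE]
  tri <- matrix(map[all_tri], ncol = 3L)
  segs <- do.call(rbind, seg_rows)
  segs$v1 <- map[segs$v1]; segs$v2 <- map[segs$v2]
  dup <- duplicated(paste(pmin(segs$v1, segs$v2), pmax(segs$v1, segs$v2)))
  segs <- segs[!dup, , drop = FALSE]
  z_fixed <- logical(nrow(verts))
  z_fixed[c(segs$v1, segs$v2)] <- TRUE
  outer <- logical(nrow(verts))
  outer[c(segs$v1[!segs$shared], segs$v2[!segs$shared])] <- TRUE
  mesh <- surface_mesh(cbind(verts, 0), tri, cell = all_cell,
                       z_fixed = z_fixed, outer = outer,
                       boundary_segments = segs, closed = FALSE)
  list(mesh = mesh, missing = NULL)
}

# Laplacian smoothing of non-boundary vertices with a fold-over guard
smooth_mesh <- function(mesh, iters) {
  V <- nrow(mesh$vertices)
  ed <- mesh_unique_edges(mesh$triangles)
  interior <- which(!mesh$z_fixed)
  if (!length(interior)) return(mesh)
  for (it in seq_len(iters)) {
    X <- mesh$vertices
    sx <- rowsum(c(X[ed[, 2L], 1L], X[ed[, 1L], 1L]), c(ed[, 1L], ed[, 2L]),
                 reorder = FALSE)
    sy <- rowsum(c(X[ed[, 2L], 2L], X[ed[, 1L], 2L]), c(ed[, 1L], ed[, 2L]),
                 reorder = FALSE)
    idx <- as.integer(rownames(sx))
    deg <- tabulate(c(ed[, 1L], ed[, 2L]), nbins = V)
    newX <- X
    newX[idx, 1L] <- sx / deg[idx]
    newX[idx, 2L] <- sy / deg[idx]
    Xc <- X
    Xc[interior, 1:2] <- newX[interior, 1:2]
    # revert vertices of any flipped / collapsed triangle
    t1 <- mesh$triangles[, 1L]; t2 <- mesh$triangles[, 2L]; t3 <- mesh$triangles[, 3L]
    a2 <- (Xc[t2, 1L] - Xc[t1, 1L]) * (Xc[t3, 2L] - Xc[t1, 2L]) -
      (Xc[t3, 1L] - Xc[t1, 1L]) * (Xc[t2, 2L] - Xc[t1, 2L])
    badv <- unique(c(t1[a2 <= 1e-12], t2[a2 <= 1e-12], t3[a2 <= 1e-12]))
    if (length(badv)) Xc[badv, ] <- X[badv, ]
    mesh$vertices <- Xc
  }
  mesh
}

#' Attach anticlinal-wall beam elements to a template mesh
#'
#' One axial beam per cell-boundary mesh edge, with the matrix Young's
#' modulus and a thickness of `beam_fraction` of the wall thickness
#' (defaults: 40 MPa and 0.2 um).
#'
#' @param mesh a [mesh_surface()] template mesh (needs `boundary_segments`).
#' @param material a [material_params()] object.
#' @return the mesh with a `beams` data.frame
#'   (`v1`, `v2`, `modulus`, `thickness`, `cell_a`, `cell_b`).
#' @export
add_anticlinal_beams <- function(mesh, material) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(mesh$boundary_segments))
    stop("mesh has no recorded cell-boundary segments")
  segs <- mesh$boundary_segments
  mesh$beams <- data.frame(
    v1 = segs$v1, v2 = segs$v2,
    modulus = material$E_matrix,
    thickness = material$beam_fraction * material$wall_thickness,
    cell_a = segs$cell_a, cell_b = segs$cell_b)
  mesh
}

#' Project a flat mesh onto a height field
#'
#' Sets every vertex z to the bilinear interpolation of `heights` at its
#' (x, y); in-plane coordinates are unchanged.
#'
#' @param mesh a `surface_mesh`.
#' @param heights list with `x` (length nx), `y` (length ny) grid coordinates
#'   and `z` (nx x ny matrix) of surface heights (um).
#' @return the projected mesh.
#' @export
project_to_heightmap <- function(mesh, heights) {
  stopifnot(is.list(heights), !is.null(heights$x), !is.null(heights$y),
            is.matrix(heights$z))
  x <- mesh$vertices[, 1L]; y <- mesh$vertices[, 2L]
  gx <- heights$x; gy <- heights$y
  if (min(x) < min(gx) - 1e-9 || max(x) > max(gx) + 1e-9 ||
      min(y) < min(gy) - 1e-9 || max(y) > max(gy) + 1e-9)
    stop("mesh footprint extends outside the height field")
  ix <- pmin(pmax(findInterval(x, gx), 1L), length(gx) - 1L)
  iy <- pmin(pmax(findInterval(y, gy), 1L), length(gy) - 1L)
  tx <- (x - gx[ix]) / (gx[ix + 1L] - gx[ix])
  ty <- (y - gy[iy]) / (gy[iy + 1L] - gy[iy])
  z <- (1 - tx) * (1 - ty) * heights$z[cbind(ix, iy)] +
    tx * (1 - ty) * heights$z[cbind(ix + 1L, iy)] +
    (1 - tx) * ty * heights$z[cbind(ix, iy + 1L)] +
    tx * ty * heights$z[cbind(ix + 1L, iy + 1L)]
  mesh$vertices[, 3L] <- z
  mesh
}
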