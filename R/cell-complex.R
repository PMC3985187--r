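# The tissue template: planar polygonal cells with shared-edge adjacency and
# an outer boundary. This replaces boundary extraction from segmented
# microscopy; the package accepts polygons from any source.

#' Build a cell complex from polygon rings
#'
#' Snaps near-identical vertices across cells (tolerance
#' `snap_tol`, default 1e-6 of the bounding-box diagonal), identifies
#' edges shared by two cells, and chains the unshared edges into the closed
#' outer boundary. Rings are re-oriented counter-clockwise.
#'
#' @param polygons list of n x 2 vertex matrices (micrometers), one per cell.
#'   Rings must be simple; interiors must not overlap.
#' @param snap_tol vertex snapping tolerance; `NULL` for the default.
#' @return an object of class `cell_complex` with elements
#'   `cells` (list of rings of snapped vertex ids), `vertices` (V x 2 matrix),
#'   `edges` (data.frame: `v1`, `v2`, `cell_a`, `cell_b`, `shared`),
#'   `adjacency` (data.frame of cell pairs), `outer_boundary`
#'   (closed chain of vertex ids).
#' @export
build_cell_complex <- function(polygons, snap_tol = NULL) {
  if (!is.list(polygons) || length(polygons) < 1L)
    stop("polygons must be a non-empty list of rings")
  rings <- lapply(polygons, function(r) ensure_ccw(as_ring(r)))
  for (i in seq_along(rings))
    if (!is_simple_polygon(rings[[i]]))
      stop("ring ", i, " is not a simple polygon")
  allxy <- do.call(rbind, rings)
  diag_len <- sqrt(sum((apply(allxy, 2L, max) - apply(allxy, 2L, min))^2))
  if (is.null(snap_tol)) snap_tol <- 1e-6 * max(diag_len, 1)

  # snap vertices by rounding onto a grid finer than snap_tol, then hashing
  key <- paste(round(allxy[, 1L] / snap_tol), round(allxy[, 2L] / snap_tol))
  uid <- match(key, unique(key))
  vertices <- rowsum(allxy, uid) / as.vector(table(uid)[as.character(sort(unique(uid)))])
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL

  cells <- vector("list", length(rings))
  off <- 0L
  for (i in seq_along(rings)) {
    n <- nrow(rings[[i]])
    ids <- uid[off + seq_len(n)]
    ids <- ids[c(TRUE, ids[-1L] != ids[-n])]          # drop snapped duplicates
    if (ids[1L] == ids[length(ids)]) ids <- ids[-length(ids)]
    if (length(ids) < 3L) stop("ring ", i, " collapsed under snapping")
    cells[[i]] <- ids
    off <- off + n
  }

  # conforming repair: a vertex of one cell may lie in the interior of
  # another cell's edge (T-junction from independent clipping); split such
  # edges so shared walls match segment by segment
  cells <- conform_cells(cells, vertices, snap_tol)

  # directed edge table per cell; undirected key pairs shared edges
  ecell <- integer(0); ev1 <- integer(0); ev2 <- integer(0)
  for (i in seq_along(cells)) {
    ids <- cells[[i]]
    n <- length(ids)
    ev1 <- c(ev1, ids); ev2 <- c(ev2, c(ids[-1L], ids[1L]))
    ecell <- c(ecell, rep.int(i, n))
  }
  ukey <- paste(pmin(ev1, ev2), pmax(ev1, ev2))
  cnt <- table(ukey)
  if (any(cnt > 2L)) stop("an edge is shared by more than two cells; inputs overlap")
  first <- match(ukey, ukey)
  shared <- as.vector(cnt[ukey]) == 2L
  is_first <- first == seq_along(ukey)
  other <- rep(NA_integer_, length(ukey))
  for (k in which(!is_first)) other[first[k]] <- ecell[k]
  edges <- data.frame(
    v1 = ev1[is_first], v2 = ev2[is_first],
    cell_a = ecell[is_first], cell_b = other[is_first],
    shared = shared[is_first]
  )

  # overlap sanity: each cell's centroid must not be interior to another cell
  for (i in seq_along(cells)) {
    ci <- polygon_centroid(vertices[cells[[i]], , drop = FALSE])
    for (j in seq_along(cells)) {
      if (i == j) next
      if (points_in_polygon(ci[1L], ci[2L], vertices[cells[[j]], , drop = FALSE]))
        stop("cells ", i, " and ", j, " have overlapping interiors")
    }
  }

  outer <- chain_boundary(edges[!edges$shared, c("v1", "v2"), drop = FALSE])
  adj <- unique(edges[edges$shared, c("cell_a", "cell_b")])
  rownames(adj) <- NULL
  structure(
    list(cells = cells, vertices = vertices, edges = edges,
         adjacency = adj, outer_boundary = outer, snap_tol = snap_tol),
    class = "cell_complex"
  )
}

# split cell-ring edges at snapped vertices lying on their interior
conform_cells <- function(cells, vertices, tol) {
  vx <- vertices[, 1L]; vy <- vertices[, 2L]
  lapply(cells, function(ids) {
    n <- length(ids)
    out <- integer(0)
    for (i in seq_len(n)) {
      u <- ids[i]; v <- ids[if (i == n) 1L else i + 1L]
      a <- vertices[u, ]; b <- vertices[v, ]
      d <- dist_point_segment(vx, vy, a, b)
      hit <- which(d < 2 * tol)
      hit <- setdiff(hit, c(u, v))
      out <- c(out, u)
      if (length(hit)) {
        ab <- b - a
        l2 <- sum(ab^2)
        t <- ((vx[hit] - a[1L]) * ab[1L] + (vy[hit] - a[2L]) * ab[2L]) / l2
        keep <- t > 1e-9 & t < 1 - 1e-9
        if (any(keep)) out <- c(out, hit[keep][order(t[keep])])
      }
    }
    out
  })
}

# chain undirected boundary segments into a closed vertex loop
chain_boundary <- function(segs) {
  if (nrow(segs) == 0L) return(integer(0))
  nbr <- split(c(segs$v2, segs$v1), c(segs$v1, segs$v2))
  start <- segs$v1[1L]
  chain <- c(start)
  prev <- -1L
  cur <- start
  repeat {
    nb <- nbr[[as.character(cur)]]
    nxt <- nb[nb != prev][1L]
    if (is.null(nxt) || is.na(nxt)) stop("outer boundary is not a closed chain")
    if (nxt == start) break
    chain <- c(chain, nxt)
    prev <- cur; cur <- nxt
    if (length(chain) > 2L * nrow(segs)) stop("outer boundary is not a single closed loop")
  }
  chain
}

#' Cell ring coordinates from a complex
#' @param complex a `cell_complex`.
#' @param cell cell index.
#' @return n x 2 matrix of vertex coordinates.
#' @export
cell_ring <- function(complex, cell) {
  complex$vertices[complex$cells[[cell]], , drop = FALSE]
}

#' @export
print.cell_complex <- function(x, ...) {
  cat("cell_complex:", length(x$cells), "cells,",
      nrow(x$vertices), "vertices,",
      sum(x$edges$shared), "shared edges, outer boundary of",
      length(x$outer_boundary), "vertices\n")
  invisible(x)
}

#' Total area of a complex (sum of cell areas)
#' @param complex a `cell_complex`.
#' @return numeric scalar.
#' @export
complex_area <- function(complex) {
  sum(vapply(seq_along(complex$cells),
             function(i) abs(polygon_area(cell_ring(complex, i))), 0))
}
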