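# Planar polygon primitives shared by the generators, the mesher and the
# scoring code. Polygons are n x 2 matrices of vertices in order, implicitly
# closed (first vertex not repeated), coordinates in micrometers unless a
# caller says otherwise.

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise rings in the package's z-up, right-handed
#' convention.
#'
#' @param ring numeric matrix, n x 2, vertices in order (not repeated).
#' @return signed area (square units of the input).
#' @export
polygon_area <- function(ring) {
  ring <- as_ring(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon centroid (area-weighted)
#' @param ring n x 2 vertex matrix.
#' @return length-2 numeric.
#' @export
polygon_centroid <- function(ring) {
  ring <- as_ring(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(ring))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

as_ring <- function(ring) {
  ring <- as.matrix(ring)
  storage.mode(ring) <- "double"
  if (ncol(ring) != 2L || nrow(ring) < 3L)
    stop("a polygon ring needs an n x 2 matrix with n >= 3")
  # drop a duplicated closing vertex if present
  n <- nrow(ring)
  if (sqrt(sum((ring[1L, ] - ring[n, ])^2)) < 1e-12 * (1 + max(abs(ring))))
    ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3L) stop("degenerate ring")
  ring
}

ensure_ccw <- function(ring) {
  ring <- as_ring(ring)
  if (polygon_area(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
}

#' Point-in-polygon test
#'
#' Even-odd rule, vectorized over query points. Points on the boundary may
#' land on either side; callers that care use a tolerance band.
#'
#' @param px,py numeric vectors of query coordinates.
#' @param ring n x 2 vertex matrix.
#' @return logical vector.
#' @export
points_in_polygon <- function(px, py, ring) {
  ring <- as_ring(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- length(x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    yi <- y[i]; yj <- y[j]; xi <- x[i]; xj <- x[j]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) * (xj - xi) / (yj - yi)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

# distance from points to a segment a-b (vectorized over points)
dist_point_segment <- function(px, py, a, b) {
  dx <- b[1L] - a[1L]; dy <- b[2L] - a[2L]
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return(sqrt((px - a[1L])^2 + (py - a[2L])^2))
  t <- pmin(1, pmax(0, ((px - a[1L]) * dx + (py - a[2L]) * dy) / l2))
  sqrt((px - (a[1L] + t * dx))^2 + (py - (a[2L] + t * dy))^2)
}

# distance from one point to a polyline (m x 2), plus nearest-segment info
dist_point_polyline <- function(p, poly, closed = TRUE) {
  n <- nrow(poly)
  idx <- if (closed) cbind(seq_len(n), c(seq_len(n)[-1L], 1L)) else
    cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  best <- Inf; bseg <- 1L; bt <- 0
  for (k in seq_len(nrow(idx))) {
    a <- poly[idx[k, 1L], ]; b <- poly[idx[k, 2L], ]
    dx <- b[1L] - a[1L]; dy <- b[2L] - a[2L]
    l2 <- dx * dx + dy * dy
    t <- if (l2 == 0) 0 else min(1, max(0, ((p[1L] - a[1L]) * dx + (p[2L] - a[2L]) * dy) / l2))
    d <- sqrt((p[1L] - (a[1L] + t * dx))^2 + (p[2L] - (a[2L] + t * dy))^2)
    if (d < best) { best <- d; bseg <- k; bt <- t }
  }
  a <- poly[idx[bseg, 1L], ]; b <- poly[idx[bseg, 2L], ]
  tangent <- b - a
  nt <- sqrt(sum(tangent^2))
  if (nt > 0) tangent <- tangent / nt
  list(dist = best, segment = bseg, t = bt, tangent = tangent)
}

# do segments p1-p2 and p3-p4 properly intersect (excluding shared endpoints)?
segments_intersect <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  ((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
    ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))
}

cross2 <- function(u, v) u[1L] * v[2L] - u[2L] * v[1L]

#' Is a ring a simple (non-self-intersecting) polygon?
#' @param ring n x 2 vertex matrix.
#' @return logical scalar.
#' @export
is_simple_polygon <- function(ring) {
  ring <- as_ring(ring)
  n <- nrow(ring)
  nxt <- c(seq_len(n)[-1L], 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      # skip adjacent edges (share a vertex)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (segments_intersect(ring[i, ], ring[nxt[i], ], ring[j, ], ring[nxt[j], ]))
        return(FALSE)
    }
  }
  TRUE
}

# Sutherland-Hodgman clip of a convex/any polygon by half-plane
# {x : (x - p) . n <= 0}; returns possibly empty matrix
clip_halfplane <- function(ring, p, nrm) {
  n <- nrow(ring)
  out <- matrix(0, 2L * n, 2L)
  m <- 0L
  sgn <- (ring[, 1L] - p[1L]) * nrm[1L] + (ring[, 2L] - p[2L]) * nrm[2L]
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ci <- sgn[i] <= 0; cj <- sgn[j] <= 0
    if (ci) { m <- m + 1L; out[m, ] <- ring[i, ] }
    if (ci != cj) {
      t <- sgn[i] / (sgn[i] - sgn[j])
      m <- m + 1L
      out[m, ] <- ring[i, ] + t * (ring[j, ] - ring[i, ])
    }
  }
  out[seq_len(m), , drop = FALSE]
}

# deduplicate consecutive (and closing) near-identical vertices
dedupe_ring <- function(ring, tol = 1e-9) {
  n <- nrow(ring)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep[i] && sqrt(sum((ring[i, ] - ring[j, ])^2)) < tol) keep[j] <- FALSE
  }
  ring[keep, , drop = FALSE]
}
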