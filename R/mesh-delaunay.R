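# Bowyer-Watson Delaunay triangulation, vectorized over the triangle store.
# Used by the constrained cell mesher; point counts per cell are a few
# hundred to a few thousand.

delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points")
  cmin <- apply(pts, 2L, min); cmax <- apply(pts, 2L, max)
  c0 <- (cmin + cmax) / 2
  d <- max(cmax - cmin, 1e-9) * 20 + 1
  P <- rbind(pts,
             c(c0[1L] - d, c0[2L] - 0.6 * d),
             c(c0[1L] + d, c0[2L] - 0.6 * d),
             c(c0[1L], c0[2L] + d))
  cap <- 4L * n + 64L
  tv <- matrix(0L, cap, 3L)
  ccx <- numeric(cap); ccy <- numeric(cap); r2 <- numeric(cap)
  active <- logical(cap)
  put <- function(k, a, b, c) {
    tv[k, ] <<- c(a, b, c)
    ax <- P[a, 1L]; ay <- P[a, 2L]; bx <- P[b, 1L]; by <- P[b, 2L]
    cx <- P[c, 1L]; cy <- P[c, 2L]
    dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(dd) < 1e-14 * (abs(ax) + abs(bx) + abs(cx) + 1)^2) {
      active[k] <<- FALSE
      return(invisible(FALSE))
    }
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / dd
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / dd
    ccx[k] <<- ux; ccy[k] <<- uy
    r2[k] <<- (ux - ax)^2 + (uy - ay)^2
    active[k] <<- TRUE
    invisible(TRUE)
  }
  put(1L, n + 1L, n + 2L, n + 3L)
  ntri <- 1L
  free <- integer(0)
  for (p in seq_len(n)) {
    px <- P[p, 1L]; py <- P[p, 2L]
    idx <- seq_len(ntri)
    bad <- idx[active[idx] &
                 ((px - ccx[idx])^2 + (py - ccy[idx])^2 <= r2[idx] * (1 + 1e-12))]
    if (length(bad) == 0L) next # degenerate (duplicate point); skip
    # cavity boundary = directed edges of bad triangles whose undirected key
    # appears once
    e1 <- c(tv[bad, 1L], tv[bad, 2L], tv[bad, 3L])
    e2 <- c(tv[bad, 2L], tv[bad, 3L], tv[bad, 1L])
    key <- paste(pmin(e1, e2), pmax(e1, e2))
    once <- key %in% names(which(table(key) == 1L))
    active[bad] <- FALSE
    free <- c(free, bad)
    for (k in which(once)) {
      slot <- if (length(free)) {
        s <- free[length(free)]; free <- free[-length(free)]; s
      } else {
        ntri <- ntri + 1L
        if (ntri > nrow(tv)) {
          grow <- nrow(tv)
          tv <- rbind(tv, matrix(0L, grow, 3L))
          ccx <- c(ccx, numeric(grow)); ccy <- c(ccy, numeric(grow))
          r2 <- c(r2, numeric(grow)); active <- c(active, logical(grow))
        }
        ntri
      }
      put(slot, e1[k], e2[k], p)
    }
  }
  keep <- active[seq_len(ntri)] &
    tv[seq_len(ntri), 1L] <= n & tv[seq_len(ntri), 2L] <= n &
    tv[seq_len(ntri), 3L] <= n
  tri <- tv[seq_len(ntri), , drop = FALSE][keep, , drop = FALSE]
  # orient counter-clockwise
  a <- tri[, 1L]; b <- tri[, 2L]; ccc <- tri[, 3L]
  det2 <- (P[b, 1L] - P[a, 1L]) * (P[ccc, 2L] - P[a, 2L]) -
    (P[ccc, 1L] - P[a, 1L]) * (P[b, 2L] - P[a, 2L])
  flip <- det2 < 0
  if (any(flip)) tri[flip, c(2L, 3L)] <- tri[flip, c(3L, 2L)]
  tri
}
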