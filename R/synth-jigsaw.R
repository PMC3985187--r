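# Synthetic pavement-cell geometry: a Voronoi partition of a square domain
# whose interior walls are modulated by a windowed sinusoid, producing the
# alternating lobe (outgrowth) / neck (indentation) pattern of leaf epidermal
# cells. Ground-truth lobe/neck landmarks are attached so downstream stress
# tests can query "neck-adjacent" regions without image analysis.

#' Parameters for the jigsaw pavement-cell generator
#'
#' @param n_cells number of cells (>= 1).
#' @param domain_size side length of the square tissue patch (micrometers).
#' @param lobe_amplitude amplitude of the wall undulation (micrometers);
#'   must be smaller than `lobe_wavelength`.
#' @param lobe_wavelength wavelength of the wall undulation (micrometers).
#' @param seed integer RNG seed; identical seeds give identical tissues.
#' @return a `jigsaw_params` list.
#' @export
jigsaw_params <- function(n_cells = 6L, domain_size = 100, lobe_amplitude = 3,
                          lobe_wavelength = 15, seed = 1L) {
  stopifnot(n_cells >= 1L, domain_size > 0, lobe_amplitude >= 0,
            lobe_wavelength > 0)
  if (lobe_amplitude >= lobe_wavelength)
    stop("lobe_amplitude must be smaller than lobe_wavelength")
  structure(list(n_cells = as.integer(n_cells), domain_size = domain_size,
                 lobe_amplitude = lobe_amplitude,
                 lobe_wavelength = lobe_wavelength, seed = as.integer(seed)),
            class = "jigsaw_params")
}

#' Generate a jigsaw pavement-cell tissue
#'
#' Seeds a jittered-grid point set, builds its Voronoi partition of the
#' square domain by half-plane clipping, then displaces every interior wall
#' by a sinusoid windowed to vanish at wall junctions (so three-cell
#' junctions stay put and the tiling is exact). If a modulated ring
#' self-intersects the amplitude is damped by 0.6 and the modulation is
#' retried (up to 8 times) before failing.
#'
#' @param params a [jigsaw_params()] object.
#' @return a [build_cell_complex()] `cell_complex`; attribute `landmarks` is a
#'   data.frame of lobe/neck wall extrema (`x`, `y`, `nx`, `ny` the unit axis
#'   pointing into the indented cell, `neck_cell`, `lobe_cell`, `depth`), and
#'   attribute `params` echoes the generator parameters.
#' @export
make_jigsaw_cells <- function(params) {
  stopifnot(inherits(params, "jigsaw_params"))
  with_seed(params$seed, {
    L <- params$domain_size
    pts <- jitter_grid_seeds(params$n_cells, L)
    rings <- voronoi_rings(pts, L)
    base <- build_cell_complex(rings)
    amp <- params$lobe_amplitude
    for (attempt in seq_len(9L)) {
      mod <- modulate_complex(base, amp, params$lobe_wavelength)
      if (!is.null(mod)) {
        cx <- build_cell_complex(mod$rings)
        attr(cx, "landmarks") <- mod$landmarks
        attr(cx, "params") <- params
        return(cx)
      }
      message("jigsaw: self-intersection at amplitude ", signif(amp, 3),
              ", damping")
      amp <- amp * 0.6
    }
    stop("could not generate a simple jigsaw tiling; reduce lobe_amplitude")
  })
}

jitter_grid_seeds <- function(n, L) {
  g <- ceiling(sqrt(n))
  sp <- L / g
  gx <- rep(seq_len(g), g); gy <- rep(seq_len(g), each = g)
  x <- (gx - 0.5) * sp; y <- (gy - 0.5) * sp
  pick <- sample.int(g * g, n)
  cbind(x[pick] + runif(n, -0.3, 0.3) * sp,
        y[pick] + runif(n, -0.3, 0.3) * sp)
}

# Voronoi cells clipped to [0,L]^2, one convex ring per seed
voronoi_rings <- function(pts, L) {
  n <- nrow(pts)
  box <- rbind(c(0, 0), c(L, 0), c(L, L), c(0, L))
  lapply(seq_len(n), function(i) {
    ring <- box
    for (j in seq_len(n)) {
      if (j == i || nrow(ring) < 3L) next
      mid <- (pts[i, ] + pts[j, ]) / 2
      nrm <- pts[j, ] - pts[i, ]          # keep side closer to seed i
      ring <- clip_halfplane(ring, mid, nrm)
      if (nrow(ring) >= 3L) ring <- dedupe_ring(ring, 1e-9 * L)
    }
    if (nrow(ring) < 3L) stop("degenerate Voronoi cell (coincident seeds?)")
    ring
  })
}

# displace shared edges; returns NULL if any modulated ring self-intersects
modulate_complex <- function(complex, amplitude, wavelength) {
  edges <- complex$edges
  V <- complex$vertices
  n_e <- nrow(edges)
  polylines <- vector("list", n_e)
  lm <- list()
  phases <- runif(n_e, 0, 2 * pi)
  for (k in seq_len(n_e)) {
    a <- V[edges$v1[k], ]; b <- V[edges$v2[k], ]
    len <- sqrt(sum((b - a)^2))
    if (!edges$shared[k] || amplitude <= 0 || len < 0.5 * wavelength) {
      polylines[[k]] <- rbind(a, b)
      next
    }
    m <- max(13L, 2L * ceiling(len / (wavelength / 8)) + 1L)
    s <- seq(0, 1, length.out = m)
    t <- (b - a) / len
    nrm <- c(-t[2L], t[1L])               # left of v1->v2 = interior of cell_a
    d <- amplitude * sin(2 * pi * s * len / wavelength + phases[k]) * sin(pi * s)
    pts <- cbind(a[1L] + s * (b[1L] - a[1L]) + d * nrm[1L],
                 a[2L] + s * (b[2L] - a[2L]) + d * nrm[2L])
    polylines[[k]] <- pts
    # landmarks: interior local extrema of the displacement
    for (i in 2:(m - 1L)) {
      if (abs(d[i]) >= abs(d[i - 1L]) && abs(d[i]) > abs(d[i + 1L]) &&
          abs(d[i]) > 0.4 * amplitude) {
        into_a <- d[i] > 0                # bows into cell_a => neck of cell_a
        axis <- if (into_a) nrm else -nrm
        lm[[length(lm) + 1L]] <- data.frame(
          x = pts[i, 1L], y = pts[i, 2L], nx = axis[1L], ny = axis[2L],
          neck_cell = if (into_a) edges$cell_a[k] else edges$cell_b[k],
          lobe_cell = if (into_a) edges$cell_b[k] else edges$cell_a[k],
          depth = abs(d[i]))
      }
    }
  }
  # rebuild rings from (possibly reversed) edge polylines
  ekey <- paste(pmin(edges$v1, edges$v2), pmax(edges$v1, edges$v2))
  rings <- vector("list", length(complex$cells))
  for (ci in seq_along(complex$cells)) {
    ids <- complex$cells[[ci]]
    n <- length(ids)
    pts <- NULL
    for (i in seq_len(n)) {
      u <- ids[i]; v <- ids[if (i == n) 1L else i + 1L]
      k <- match(paste(min(u, v), max(u, v)), ekey)
      pl <- polylines[[k]]
      if (edges$v1[k] != u) pl <- pl[rev(seq_len(nrow(pl))), , drop = FALSE]
      pts <- rbind(pts, pl[-nrow(pl), , drop = FALSE])
    }
    if (!is_simple_polygon(pts)) return(NULL)
    rings[[ci]] <- pts
  }
  landmarks <- if (length(lm)) do.call(rbind, lm) else
    data.frame(x = numeric(0), y = numeric(0), nx = numeric(0),
               ny = numeric(0), neck_cell = integer(0),
               lobe_cell = integer(0), depth = numeric(0))
  list(rings = rings, landmarks = landmarks)
}
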