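# AFM force-curve models and fits. Units: separation/indentation nm, force
# nN, moduli MPa (1 MPa = 1e-3 nN/nm^2). Two contact models:
#   Hertz-Sneddon rigid cone on the approach segment:
#     F = (2/pi) tan(alpha) * E/(1-nu^2) * delta^2
#   DMT sphere with adhesion on the retract segment:
#     F - F_adh = (4/3) E* sqrt(R) (d - d0)^(3/2),  E* = E/(1-nu^2)
# Only an "apparent modulus" Ea is reported since neither nu nor the exact
# tip shape is known; Ea = E* (1 - nu^2) recovers E under the assumed nu.

MPA_PER_NN_NM2 <- 1e3 # 1 nN/nm^2 = 1 GPa = 1000 MPa

#' Indenter tip parameters
#'
#' @param half_angle cone half-angle (degrees, 0-90).
#' @param radius sphere/tip-end radius (nm; manufacturer range 2-10).
#' @param poisson sample Poisson ratio (0.5 = incompressible).
#' @return a `tip_params`.
#' @export
tip_params <- function(half_angle = 18, radius = 6, poisson = 0.5) {
  stopifnot(half_angle > 0, half_angle < 90, radius > 0,
            poisson >= 0, poisson <= 0.5)
  structure(list(half_angle = half_angle, radius = radius, poisson = poisson),
            class = "tip_params")
}

#' A single indentation force curve
#'
#' @param separation tip-sample separation (nm), approach then retract.
#' @param force measured force (nN).
#' @param segment character vector, "approach" or "retract" per sample.
#' @param metadata optional list (spring constant, sensitivity, ...).
#' @return a `force_curve`.
#' @export
force_curve <- function(separation, force, segment, metadata = list()) {
  stopifnot(length(separation) == length(force),
            length(segment) == length(force),
            all(segment %in% c("approach", "retract")))
  if (any(segment == "approach") && any(segment == "retract") &&
      max(which(segment == "approach")) > min(which(segment == "retract")))
    stop("approach samples must precede retract samples")
  structure(list(separation = as.numeric(separation),
                 force = as.numeric(force), segment = segment,
                 metadata = metadata), class = "force_curve")
}

hertz_cone_prefactor <- function(E_mpa, tip) {
  (2 / pi) * tan(tip$half_angle * pi / 180) *
    (E_mpa / MPA_PER_NN_NM2) / (1 - tip$poisson^2)
}

dmt_prefactor <- function(Estar_mpa, tip) {
  (4 / 3) * (Estar_mpa / MPA_PER_NN_NM2) * sqrt(tip$radius)
}

#' Evaluate the forward contact models
#'
#' @param delta indentation depth (nm, >= 0).
#' @param E modulus: Young's modulus (MPa) for `hertz_cone`; for
#'   `dmt_sphere` the Young's modulus converted internally to
#'   `E* = E/(1-nu^2)`.
#' @param tip a [tip_params()].
#' @param model `"hertz_cone"` or `"dmt_sphere"`.
#' @param adhesion_force adhesion well depth (nN, DMT only).
#' @return force (nN).
#' @export
contact_force <- function(delta, E, tip, model = c("hertz_cone", "dmt_sphere"),
                          adhesion_force = 0) {
  model <- match.arg(model)
  delta <- pmax(delta, 0)
  if (model == "hertz_cone") {
    hertz_cone_prefactor(E, tip) * delta^2
  } else {
    Estar <- E / (1 - tip$poisson^2)
    -adhesion_force + dmt_prefactor(Estar, tip) * delta^1.5
  }
}

#' Specification of a synthetic force-curve grid
#'
#' @param grid_shape c(rows, cols) of the scan (default 128 x 128).
#' @param modulus_map matrix of ground-truth Young's moduli (MPa), recycled
#'   to the grid shape.
#' @param model `"hertz_cone"` or `"dmt_sphere"`.
#' @param tip a [tip_params()].
#' @param adhesion_force adhesion (nN, DMT retract well).
#' @param noise_sd force noise: standard deviation in nN (`additive`) or as
#'   a fraction of the local force (`multiplicative`).
#' @param noise_type `"additive"` or `"multiplicative"`.
#' @param max_indent maximum indentation depth (nm).
#' @param n_points samples per segment.
#' @param height_map optional topography (nm), recycled; shifts the contact
#'   point.
#' @param seed RNG seed.
#' @return a `curve_grid_spec`.
#' @export
curve_grid_spec <- function(grid_shape = c(128L, 128L), modulus_map = 4,
                            model = c("hertz_cone", "dmt_sphere"),
                            tip = tip_params(), adhesion_force = 0.5,
                            noise_sd = 0,
                            noise_type = c("additive", "multiplicative"),
                            max_indent = 100, n_points = 120L,
                            height_map = 0, seed = 1L) {
  model <- match.arg(model)
  noise_type <- match.arg(noise_type)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1L))
  mm <- matrix(modulus_map, grid_shape[1L], grid_shape[2L])
  if (any(mm <= 0)) stop("moduli must be positive")
  hm <- matrix(height_map, grid_shape[1L], grid_shape[2L])
  structure(list(grid_shape = grid_shape, modulus_map = mm, model = model,
                 tip = tip, adhesion_force = adhesion_force,
                 noise_sd = noise_sd, noise_type = noise_type,
                 max_indent = max_indent,
                 n_points = as.integer(n_points), height_map = hm,
                 seed = as.integer(seed)),
            class = "curve_grid_spec")
}

# one synthetic curve; d0 = contact point on the separation axis
synth_curve <- function(E, spec, d0 = 0) {
  span <- spec$max_indent
  # odd count so the contact point itself is sampled (exact model minimum)
  s_app <- seq(d0 + span, d0 - span, length.out = 2L * spec$n_points + 1L)
  delta <- pmax(d0 - s_app, 0)
  if (spec$model == "hertz_cone") {
    f_app <- contact_force(delta, E, spec$tip, "hertz_cone")
    f_ret <- rev(f_app)
  } else {
    f_app <- contact_force(delta, E, spec$tip, "hertz_cone") # approach: repulsive
    fr <- contact_force(rev(delta), E, spec$tip, "dmt_sphere",
                        adhesion_force = spec$adhesion_force)
    s_ret <- rev(s_app)
    tail_region <- s_ret > d0
    fr[tail_region] <- -spec$adhesion_force *
      exp(-(s_ret[tail_region] - d0) / 5)
    f_ret <- fr
  }
  sep <- c(s_app, rev(s_app))
  force <- c(f_app, f_ret)
  if (spec$noise_sd > 0) {
    force <- if (identical(spec$noise_type, "multiplicative"))
      force * (1 + rnorm(length(force), 0, spec$noise_sd))
    else force + rnorm(length(force), 0, spec$noise_sd)
  }
  force_curve(sep, force,
              rep(c("approach", "retract"), each = 2L * spec$n_points + 1L))
}

#' Generate a grid of synthetic force curves
#'
#' Noiseless contact forces follow the selected model exactly; the DMT
#' retract carries an adhesion well whose minimum is `-adhesion_force`.
#' Contact points are offset by the per-pixel topography.
#'
#' @param spec a [curve_grid_spec()].
#' @return a `force_curve_grid`: list `curves` (row-major list of
#'   [force_curve()]), `shape`, `spec`.
#' @export
make_force_curves <- function(spec) {
  stopifnot(inherits(spec, "curve_grid_spec"))
  with_seed(spec$seed, {
    nr <- spec$grid_shape[1L]; nc <- spec$grid_shape[2L]
    curves <- vector("list", nr * nc)
    for (i in seq_len(nr))
      for (j in seq_len(nc))
        curves[[(i - 1L) * nc + j]] <-
          synth_curve(spec$modulus_map[i, j], spec, d0 = spec$height_map[i, j])
    structure(list(curves = curves, shape = spec$grid_shape, spec = spec),
              class = "force_curve_grid")
  })
}

# piecewise (flat baseline | power-law contact) least squares at fixed d0;
# returns c(sse, baseline, k)
piecewise_fit <- function(s, f, d0, p) {
  delta <- pmax(d0 - s, 0)
  x <- delta^p
  # linear LS for f = b + k x
  n <- length(x)
  sx <- sum(x); sxx <- sum(x * x); sf <- sum(f); sxf <- sum(x * f)
  det <- n * sxx - sx * sx
  if (det <= 1e-300) return(c(Inf, 0, 0))
  b <- (sxx * sf - sx * sxf) / det
  k <- (n * sxf - sx * sf) / det
  r <- f - b - k * x
  c(sum(r * r), b, k)
}

fit_power_contact <- function(s, f, p) {
  # coarse contact estimate: first sample (scanning down) where force rises
  # clearly above the far-field baseline; the power-law onset is shallow, so
  # the search window extends well before the crossing
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; f <- f[ord]
  n <- length(s)
  nb <- max(5L, floor(n / 5))
  base <- stats::median(f[seq_len(nb)])
  noise <- stats::mad(f[seq_len(nb)]) + 1e-12
  thr <- base + max(5 * noise, 0.02 * (max(f) - base))
  idx <- which(f > thr)
  if (!length(idx) || max(f) - base <= 1e-9)
    stop("no contact detected in the curve")
  i0 <- idx[1L]
  lo <- max(1L, i0 - ceiling(0.4 * n)); hi <- min(n, i0 + ceiling(0.05 * n))
  scan <- function(cand) {
    best <- c(Inf, 0, 0); bestd0 <- NA_real_
    for (d0 in cand) {
      r <- piecewise_fit(s, f, d0, p)
      if (r[1L] < best[1L]) { best <- r; bestd0 <- d0 }
    }
    list(best = best, d0 = bestd0)
  }
  res <- scan(s[lo:hi])
  dx <- stats::median(abs(diff(s))) # sample spacing
  for (w in c(1.2 * dx, 0.12 * dx)) {
    res2 <- scan(seq(res$d0 - w, res$d0 + w, length.out = 25L))
    if (res2$best[1L] < res$best[1L]) res <- res2
  }
  sst <- sum((f - mean(f))^2)
  list(contact_point = res$d0, baseline = res$best[2L], k = res$best[3L],
       r_squared = if (sst > 0) 1 - res$best[1L] / sst else NA_real_)
}

#' Fit the Hertz-Sneddon cone model to an approach curve
#'
#' Contact point by piecewise (flat baseline + quadratic) grid search, then
#' the apparent modulus from the quadratic coefficient:
#' `Ea = k pi (1 - nu^2) / (2 tan(alpha))`.
#'
#' @param curve a [force_curve()].
#' @param tip a [tip_params()].
#' @return list: `Ea` (MPa), `contact_point` (nm), `r_squared`, `failed`.
#' @export
fit_hertz_cone <- function(curve, tip) {
  stopifnot(inherits(curve, "force_curve"), inherits(tip, "tip_params"))
  sel <- curve$segment == "approach"
  if (!any(sel)) stop("curve has no approach segment")
  fit <- fit_power_contact(curve$separation[sel], curve$force[sel], 2)
  k <- fit$k
  failed <- !is.finite(k) || k <= 0
  Ea <- if (failed) NA_real_ else
    k * pi * (1 - tip$poisson^2) / (2 * tan(tip$half_angle * pi / 180)) *
    MPA_PER_NN_NM2
  list(Ea = Ea, contact_point = fit$contact_point,
       r_squared = fit$r_squared, failed = failed)
}

#' Fit the DMT sphere model to a retract curve
#'
#' The contact point is located by grid search (free-intercept fit of the
#' contact region against `(d0 - s)^(3/2)`); the fitted intercept is
#' `-F_adh`, which for a clean curve equals `min(retract force)` (the
#' adhesion well bottom), and under noise is the regression (noise-unbiased)
#' estimate of it. With the assumed Poisson ratio,
#' `Ea = E* (1 - nu^2)` (0.75 E* at nu = 0.5).
#'
#' @param curve a [force_curve()].
#' @param tip a [tip_params()] (radius required).
#' @return list: `E_star`, `Ea` (MPa), `F_adh` (nN), `contact_point`,
#'   `r_squared`, `failed`.
#' @export
fit_dmt_sphere <- function(curve, tip) {
  stopifnot(inherits(curve, "force_curve"), inherits(tip, "tip_params"))
  if (is.null(tip$radius) || !is.finite(tip$radius) || tip$radius <= 0)
    stop("DMT fit needs a tip radius")
  sel <- curve$segment == "retract"
  if (!any(sel)) stop("curve has no retract segment")
  ord <- order(curve$separation[sel], decreasing = TRUE)
  s <- curve$separation[sel][ord]; f <- curve$force[sel][ord]
  n <- length(s)
  if (max(f) - stats::median(f[seq_len(max(5L, n %/% 5))]) <= 1e-9)
    stop("no contact detected on the retract segment")
  # coarse contact estimate from the steep repulsive rise (robust to noise;
  # the adhesion well is shallow by comparison)
  nb <- max(5L, n %/% 5)
  base <- stats::median(f[seq_len(nb)])
  noise <- stats::mad(f[seq_len(nb)]) + 1e-12
  thr <- base + max(5 * noise, 0.02 * (max(f) - base))
  i0 <- which(f > thr)[1L]
  dx <- stats::median(abs(diff(s)))
  d0i <- s[i0]
  # refine d0: free-intercept power-law fit on the contact side only
  margin <- 2 * dx
  eval_d0 <- function(d0) {
    cont <- which(s <= d0 - margin)
    if (length(cont) < 8L) return(list(mse = Inf))
    x <- (d0 - s[cont])^1.5
    y <- f[cont]
    m <- length(x)
    sx <- sum(x); sxx <- sum(x * x); sy <- sum(y); sxy <- sum(x * y)
    det <- m * sxx - sx * sx
    if (det <= 1e-300) return(list(mse = Inf))
    c0 <- (sxx * sy - sx * sxy) / det
    k <- (m * sxy - sx * sy) / det
    r <- y - c0 - k * x
    list(mse = mean(r^2), k = k, c0 = c0, y = y, r = r)
  }
  best <- list(mse = Inf); bestd0 <- d0i
  for (d0 in seq(d0i - ceiling(0.2 * n) * dx, d0i + ceiling(0.25 * n) * dx,
                 by = dx)) {
    e <- eval_d0(d0)
    if (e$mse < best$mse) { best <- e; bestd0 <- d0 }
  }
  for (d0 in seq(bestd0 - dx, bestd0 + dx, length.out = 21L)) {
    e <- eval_d0(d0)
    if (e$mse < best$mse) { best <- e; bestd0 <- d0 }
  }
  if (!is.finite(best$mse)) stop("no contact region on the retract segment")
  k <- best$k
  F_adh <- max(-best$c0, 0) # model adhesion; equals -min(F) for clean curves
  failed <- !is.finite(k) || k <= 0
  Estar <- if (failed) NA_real_ else k * 3 / (4 * sqrt(tip$radius)) *
    MPA_PER_NN_NM2
  sst <- sum((best$y - mean(best$y))^2)
  list(E_star = Estar,
       Ea = if (failed) NA_real_ else Estar * (1 - tip$poisson^2),
       F_adh = F_adh, contact_point = bestd0,
       r_squared = if (sst > 0) 1 - sum(best$r^2) / sst else NA_real_,
       failed = failed)
}

#' Fit a whole scan grid into an apparent-modulus (stiffness) map
#'
#' @param curves a `force_curve_grid` (or list of curves plus `shape`).
#' @param tip a [tip_params()].
#' @param model `"hertz_cone"` (approach fits) or `"dmt_sphere"` (retract).
#' @return a `stiffness_map`: `Ea` (matrix, MPa, NA where the fit failed),
#'   `topography` (contact-point height, nm), `r_squared`, `shape`.
#' @export
build_stiffness_map <- function(curves, tip, model = c("hertz_cone", "dmt_sphere")) {
  model <- match.arg(model)
  stopifnot(inherits(curves, "force_curve_grid"))
  shape <- curves$shape
  if (length(curves$curves) != prod(shape))
    stop("grid shape does not match the number of curves")
  Ea <- matrix(NA_real_, shape[1L], shape[2L])
  topo <- matrix(NA_real_, shape[1L], shape[2L])
  r2 <- matrix(NA_real_, shape[1L], shape[2L])
  for (i in seq_len(shape[1L]))
    for (j in seq_len(shape[2L])) {
      cv <- curves$curves[[(i - 1L) * shape[2L] + j]]
      ft <- tryCatch(
        if (model == "hertz_cone") fit_hertz_cone(cv, tip)
        else fit_dmt_sphere(cv, tip),
        error = function(e) NULL)
      if (!is.null(ft) && !isTRUE(ft$failed)) {
        Ea[i, j] <- ft$Ea
        topo[i, j] <- ft$contact_point
        r2[i, j] <- ft$r_squared
      }
    }
  structure(list(Ea = Ea, topography = topo, r_squared = r2, shape = shape,
                 model = model), class = "stiffness_map")
}
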