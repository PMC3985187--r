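# Nonlinear membrane solver: total-potential-energy minimization by damped
# Newton iteration with an analytic sparse tangent, Armijo backtracking and a
# Levenberg-style diagonal shift for indefinite or singular tangents (flat
# starts have no out-of-plane stiffness until tension builds up).
# Pressure enters through conservative potentials, so the line search can act
# on the true objective.

#' A mechanical model: mesh + material + perturbation state
#'
#' Bundles everything [solve_model()] needs: per-element stiffness scale and
#' per-cell turgor (both modified by [ablate()]), plus beam scales.
#'
#' @param mesh a `surface_mesh` (with beams for template models).
#' @param material a [material_params()] object.
#' @return an object of class `fem_model`.
#' @export
fem_model <- function(mesh, material) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(material, "material_params"))
  cells <- sort(unique(mesh$cell))
  cp <- rep(material$turgor_P, length(cells))
  names(cp) <- as.character(cells)
  structure(list(
    mesh = mesh, material = material,
    stiffness_scale = rep(1, nrow(mesh$triangles)),
    beam_scale = if (is.null(mesh$beams)) numeric(0) else rep(1, nrow(mesh$beams)),
    cell_pressure = cp), class = "fem_model")
}

# per-element reference frames, inverse edge matrices, material coefficients
build_fem_cache <- function(mesh, material, stiffness_scale = NULL,
                            fiber = NULL, beam_scale = NULL) {
  X <- mesh$vertices
  tri <- mesh$triangles
  T <- nrow(tri)
  if (is.null(stiffness_scale)) stiffness_scale <- rep(1, T)
  if (is.null(fiber)) fiber <- mesh$fiber
  u <- X[tri[, 2L], , drop = FALSE] - X[tri[, 1L], , drop = FALSE]
  v <- X[tri[, 3L], , drop = FALSE] - X[tri[, 1L], , drop = FALSE]
  lu <- sqrt(rowSums(u^2))
  e1 <- u / lu
  nrm <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
               u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
               u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  ln <- sqrt(rowSums(nrm^2))
  if (any(ln <= 0)) stop("degenerate reference triangle")
  nrm <- nrm / ln
  e2 <- cbind(nrm[, 2L] * e1[, 3L] - nrm[, 3L] * e1[, 2L],
              nrm[, 3L] * e1[, 1L] - nrm[, 1L] * e1[, 3L],
              nrm[, 1L] * e1[, 2L] - nrm[, 2L] * e1[, 1L])
  ve1 <- rowSums(v * e1)
  ve2 <- rowSums(v * e2)            # = |u x v| / |u| > 0
  area0 <- lu * ve2 / 2
  # Dinv column-major: d11, d21, d12, d22
  Dinv <- cbind(1 / lu, 0, -ve1 / (lu * ve2), 1 / ve2)
  lp <- lame_plane_stress(material$E_matrix, material$nu_matrix)
  ze <- fiber_zeta(material)
  f1 <- rowSums(fiber * e1)
  f2 <- rowSums(fiber * e2)
  fn <- sqrt(f1^2 + f2^2)
  has_fib <- fn > 1e-8
  fib2 <- cbind(ifelse(has_fib, f1 / fn, 0), ifelse(has_fib, f2 / fn, 0))
  bars <- NULL
  if (!is.null(mesh$beams) && nrow(mesh$beams)) {
    b <- mesh$beams
    if (is.null(beam_scale)) beam_scale <- rep(1, nrow(b))
    dl <- X[b$v2, , drop = FALSE] - X[b$v1, , drop = FALSE]
    bars <- list(v1 = as.integer(b$v1 - 1L), v2 = as.integer(b$v2 - 1L),
                 L0 = sqrt(rowSums(dl^2)),
                 EA = b$modulus * beam_scale * b$thickness *
                   material$wall_thickness)
  }
  list(mesh = mesh, material = material,
       tri0 = tri - 1L,
       Dinv = Dinv, coef = area0 * mesh$thickness, area0 = area0,
       lam = lp$lambda * stiffness_scale, mu = lp$mu * stiffness_scale,
       zeta = ze * stiffness_scale * as.numeric(has_fib),
       fib2 = fib2, bars = bars,
       frames = list(e1 = e1, e2 = e2))
}

assemble_system <- function(cache, Xm, pressure, contact, want_hess) {
  mem <- fem_membrane(Xm, cache$tri0, cache$Dinv, cache$coef,
                      cache$lam, cache$mu, cache$zeta, cache$fib2, want_hess)
  energy <- mem$energy
  grad <- mem$grad
  hi <- mem$hi; hj <- mem$hj; hx <- mem$hx
  if (!is.null(cache$bars)) {
    br <- fem_bars(Xm, cache$bars$v1, cache$bars$v2, cache$bars$L0,
                   cache$bars$EA, want_hess)
    energy <- energy + br$energy
    grad <- grad + br$grad
    if (want_hess) { hi <- c(hi, br$hi); hj <- c(hj, br$hj); hx <- c(hx, br$hx) }
  }
  volume <- NA_real_
  if (!is.null(pressure) && any(pressure != 0)) {
    pr <- if (cache$mesh$closed)
      fem_pressure_closed(Xm, cache$tri0, pressure, want_hess)
    else fem_pressure_zvol(Xm, cache$tri0, pressure, want_hess)
    energy <- energy + pr$energy
    grad <- grad + pr$grad
    volume <- pr$volume
    if (want_hess) { hi <- c(hi, pr$hi); hj <- c(hj, pr$hj); hx <- c(hx, pr$hx) }
  }
  hdiag_extra <- NULL
  if (!is.null(contact)) {
    z <- Xm[, 3L]
    pen <- pmax(z - contact$gap, 0)
    energy <- energy + 0.5 * contact$k * sum(pen^2)
    gz <- contact$k * pen
    grad[seq(3L, 3L * nrow(Xm), by = 3L)] <-
      grad[seq(3L, 3L * nrow(Xm), by = 3L)] + gz
    if (want_hess) {
      act <- which(pen > 0)
      if (length(act)) {
        hi <- c(hi, 3L * act - 1L)   # 0-based z dof = 3*(v-1)+2 = 3v-1
        hj <- c(hj, 3L * act - 1L)
        hx <- c(hx, rep(contact$k, length(act)))
      }
    }
  }
  out <- list(energy = energy, grad = grad, volume = volume)
  if (want_hess) { out$hi <- hi; out$hj <- hj; out$hx <- hx }
  out
}

#' Loads and boundary conditions for a template or closed mesh
#'
#' Open templates: outer-boundary vertices get a prescribed in-plane radial
#' expansion (`boundary_expansion` about the template centroid) and are held
#' at z = 0; all cell-boundary vertices are z-fixed (the anticlinal-wall
#' restriction); uniform turgor acts on every element. Closed meshes: any
#' flagged vertices are clamped; turgor acts on the whole surface.
#'
#' @param mesh a `surface_mesh`.
#' @param material a [material_params()] object.
#' @param cell_pressure optional named per-cell pressure overriding uniform
#'   turgor (names = cell labels).
#' @return a `fem_loads` list: `fixed_idx`, `fixed_val` (absolute positions
#'   of constrained dofs), `pressure` (per element), `centroid`.
#' @export
apply_loads_and_bcs <- function(mesh, material, cell_pressure = NULL) {
  V <- nrow(mesh$vertices)
  dof <- function(v, c) 3L * (v - 1L) + c
  fixed_idx <- integer(0); fixed_val <- numeric(0)
  if (mesh$closed) {
    cl <- which(mesh$outer | mesh$z_fixed)
    if (length(cl)) {
      fixed_idx <- c(dof(cl, 1L), dof(cl, 2L), dof(cl, 3L))
      fixed_val <- c(mesh$vertices[cl, 1L], mesh$vertices[cl, 2L],
                     mesh$vertices[cl, 3L])
    }
    centroid <- colMeans(mesh$vertices[, 1:2, drop = FALSE])
  } else {
    outer <- which(mesh$outer)
    if (!length(outer)) stop("open template without a marked outer boundary")
    centroid <- colMeans(mesh$vertices[outer, 1:2, drop = FALSE])
    ex <- 1 + material$boundary_expansion
    px <- centroid[1L] + ex * (mesh$vertices[outer, 1L] - centroid[1L])
    py <- centroid[2L] + ex * (mesh$vertices[outer, 2L] - centroid[2L])
    fixed_idx <- c(dof(outer, 1L), dof(outer, 2L), dof(outer, 3L))
    fixed_val <- c(px, py, mesh$vertices[outer, 3L])
    zb <- which(mesh$z_fixed & !mesh$outer)
    fixed_idx <- c(fixed_idx, dof(zb, 3L))
    fixed_val <- c(fixed_val, mesh$vertices[zb, 3L])
  }
  pel <- if (is.null(cell_pressure)) rep(material$turgor_P, nrow(mesh$triangles))
  else as.numeric(cell_pressure[as.character(mesh$cell)])
  structure(list(fixed_idx = fixed_idx, fixed_val = fixed_val,
                 pressure = pel, centroid = centroid),
            class = "fem_loads")
}

newton_minimize <- function(cache, x0, fixed_idx, fixed_val, pressure,
                            contact, control) {
  nd <- length(x0)
  x <- x0
  if (length(fixed_idx)) x[fixed_idx] <- fixed_val
  free <- if (length(fixed_idx)) setdiff(seq_len(nd), fixed_idx) else seq_len(nd)
  Xm <- function(x) matrix(x, ncol = 3L, byrow = TRUE)
  en <- function(x) assemble_system(cache, Xm(x), pressure, contact, FALSE)$energy
  tau <- 0
  ng0 <- NA_real_
  e_prev <- Inf
  iters <- 0L
  for (it in seq_len(control$max_iter)) {
    iters <- it
    a <- assemble_system(cache, Xm(x), pressure, contact, TRUE)
    gf <- a$grad[free]
    ng <- sqrt(sum(gf^2))
    if (it == 1L) ng0 <- max(ng, 1e-300)
    if (ng < max(control$tol_rel * ng0, control$tol_abs))
      return(list(x = x, converged = TRUE, iterations = it - 1L,
                  residual = ng, energy = a$energy, volume = a$volume))
    H <- Matrix::sparseMatrix(i = a$hi + 1L, j = a$hj + 1L, x = a$hx,
                              dims = c(nd, nd))
    Hff <- H[free, free, drop = FALSE]
    dscale <- mean(abs(Matrix::diag(Hff))) + 1e-300
    d <- NULL
    tau_try <- tau
    for (k in seq_len(30L)) {
      Hs <- Matrix::forceSymmetric(Hff + Matrix::Diagonal(length(free),
                                                          tau_try * dscale))
      ch <- suppressWarnings(
        try(Matrix::Cholesky(Hs, LDL = FALSE, perm = TRUE), silent = TRUE))
      if (!inherits(ch, "try-error")) {
        dd <- as.numeric(Matrix::solve(ch, -gf))
        if (sum(dd * gf) < 0) { d <- dd; break }
      }
      tau_try <- if (tau_try == 0) 1e-8 else tau_try * 10
    }
    if (is.null(d)) stop("singular tangent: check constraints (rigid-body modes?)")
    tau <- tau_try
    # Armijo backtracking on the energy
    e0 <- a$energy
    slope <- sum(d * gf)
    alpha <- 1
    ok <- FALSE
    for (ls in seq_len(30L)) {
      xt <- x
      xt[free] <- x[free] + alpha * d
      et <- en(xt)
      if (is.finite(et) && et <= e0 + 1e-4 * alpha * slope) { ok <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!ok) {
      # stalled line search: accept tiny step only if it still decreases
      if (et >= e0) {
        if (ng < 1e3 * max(control$tol_rel * ng0, control$tol_abs))
          return(list(x = x, converged = TRUE, iterations = it,
                      residual = ng, energy = e0, volume = a$volume))
        stop("line search failed (residual ", signif(ng, 3), ")")
      }
    }
    x[free] <- x[free] + alpha * d
    if (alpha == 1 && tau > 0) tau <- tau / 10
    if (abs(e_prev - et) < control$tol_energy * (abs(et) + 1) && ng < 1e-4 * ng0)
      return(list(x = x, converged = TRUE, iterations = it, residual = ng,
                  energy = et, volume = a$volume))
    e_prev <- et
  }
  stop("Newton iteration did not converge in ", control$max_iter,
       " iterations (residual ", signif(ng, 3), ")")
}

solver_control <- function(control = list()) {
  def <- list(tol_rel = 1e-8, tol_abs = 1e-9, tol_energy = 1e-14,
              max_iter = 200L, ramp = c(0.3, 0.6, 1), lift = TRUE)
  def[names(control)] <- control
  def
}

#' Solve for mechanical equilibrium
#'
#' Minimizes total potential energy (elastic minus pressure work) with
#' damped Newton iteration: the turgor load is ramped in steps
#' (`control$ramp`), each solved to a residual below `tol_rel` times the
#' initial residual, with Armijo backtracking line search. Flat open
#' templates receive a small deterministic out-of-plane lift so the first
#' tangent is not singular in z.
#'
#' @param mesh a `surface_mesh`.
#' @param material a [material_params()] object.
#' @param loads a [apply_loads_and_bcs()] object (built from defaults when
#'   `NULL`).
#' @param control list overriding solver defaults (`tol_rel` 1e-8,
#'   `max_iter` 200, `ramp`, ...).
#' @param cache internal element cache override (used by [feedback_align()]
#'   and [ablate()]-derived solves).
#' @param init optional V x 3 initial coordinates (warm start).
#' @return a `fem_displacements` object: final coordinates `X`, `converged`,
#'   `iterations`, `residual`, `energy`, enclosed `volume` (closed meshes),
#'   and the element `cache` used (consumed by [principal_stress()]).
#' @export
solve_equilibrium <- function(mesh, material, loads = NULL, control = list(),
                              cache = NULL, init = NULL) {
  control <- solver_control(control)
  if (is.null(loads)) loads <- apply_loads_and_bcs(mesh, material)
  if (is.null(cache)) cache <- build_fem_cache(mesh, material)
  X0 <- if (is.null(init)) mesh$vertices else init
  if (control$lift && !mesh$closed && any(loads$pressure != 0) &&
      max(abs(X0[, 3L])) < 1e-12) {
    X0[, 3L] <- X0[, 3L] + flat_start_lift(mesh)
    if (length(loads$fixed_idx)) {
      x <- as.numeric(t(X0)); x[loads$fixed_idx] <- loads$fixed_val
      X0 <- matrix(x, ncol = 3L, byrow = TRUE)
    }
  }
  x <- as.numeric(t(X0))
  iters <- 0L
  res <- NULL
  for (f in control$ramp) {
    res <- newton_minimize(cache, x, loads$fixed_idx, loads$fixed_val,
                           loads$pressure * f,
                           loads$contact, control)
    x <- res$x
    iters <- iters + res$iterations
  }
  structure(list(X = matrix(x, ncol = 3L, byrow = TRUE),
                 converged = res$converged, iterations = iters,
                 residual = res$residual, energy = res$energy,
                 volume = res$volume, cache = cache, loads = loads),
            class = "fem_displacements")
}

# deterministic lift: hop distance to the nearest constrained-z vertex
flat_start_lift <- function(mesh, step = NULL) {
  V <- nrow(mesh$vertices)
  ed <- mesh_unique_edges(mesh$triangles)
  h_avg <- mean(sqrt(rowSums((mesh$vertices[ed[, 1L], , drop = FALSE] -
                                mesh$vertices[ed[, 2L], , drop = FALSE])^2)))
  if (is.null(step)) step <- 0.1 * h_avg
  dist <- rep(Inf, V)
  frontier <- which(mesh$z_fixed | mesh$outer)
  dist[frontier] <- 0
  nbr <- split(c(ed[, 2L], ed[, 1L]), c(ed[, 1L], ed[, 2L]))
  lev <- 0L
  while (length(frontier)) {
    lev <- lev + 1L
    nxt <- unique(unlist(nbr[as.character(frontier)], use.names = FALSE))
    nxt <- nxt[dist[nxt] > lev]
    dist[nxt] <- lev
    frontier <- nxt
  }
  dist[!is.finite(dist)] <- 0
  pmin(dist, 5) * step
}

#' @export
print.fem_displacements <- function(x, ...) {
  cat("fem_displacements:", nrow(x$X), "vertices;",
      if (x$converged) "converged" else "NOT converged", "in",
      x$iterations, "Newton iterations; residual", signif(x$residual, 3), "\n")
  invisible(x)
}

#' Principal membrane (Cauchy) stresses per element
#'
#' Pushes the 2nd Piola-Kirchhoff stress forward to the deformed tangent
#' plane, divides by the current thickness (plane-stress thickness stretch),
#' and eigen-decomposes. `sigma1 >= sigma2`, tension positive; direction
#' vectors are 3D unit tangents, defined up to sign. Elements with
#' `sigma1 - sigma2 < 1e-6 |sigma1|` are flagged degenerate.
#'
#' @param disp a converged [solve_equilibrium()] result.
#' @param mesh the mesh that was solved.
#' @param material a [material_params()] object.
#' @return a `stress_field` list: `sigma1`, `sigma2`, `dir1`, `dir2`,
#'   `degenerate`, `area` (deformed element areas), `centroid` (deformed),
#'   `cell`.
#' @export
principal_stress <- function(disp, mesh, material) {
  stopifnot(inherits(disp, "fem_displacements"))
  if (!isTRUE(disp$converged)) stop("displacements are not converged")
  cache <- disp$cache
  X <- disp$X
  st <- fem_element_state(X, cache$tri0, cache$Dinv, cache$lam, cache$mu,
                          cache$zeta, cache$fib2)
  T <- nrow(st)
  S11 <- st[, 1L]; S22 <- st[, 2L]; S12 <- st[, 3L]
  F1 <- st[, 4:6, drop = FALSE]; F2 <- st[, 7:9, drop = FALSE]
  # deformed tangent frame
  l1 <- sqrt(rowSums(F1^2))
  t1 <- F1 / l1
  nn <- cbind(F1[, 2L] * F2[, 3L] - F1[, 3L] * F2[, 2L],
              F1[, 3L] * F2[, 1L] - F1[, 1L] * F2[, 3L],
              F1[, 1L] * F2[, 2L] - F1[, 2L] * F2[, 1L])
  nn <- nn / sqrt(rowSums(nn^2))
  t2 <- cbind(nn[, 2L] * t1[, 3L] - nn[, 3L] * t1[, 2L],
              nn[, 3L] * t1[, 1L] - nn[, 1L] * t1[, 3L],
              nn[, 1L] * t1[, 2L] - nn[, 2L] * t1[, 1L])
  # local 2x2 deformation gradient: rows (t1, t2) . columns (F1, F2)
  a11 <- l1; a12 <- rowSums(t1 * F2)
  a21 <- 0;  a22 <- rowSums(t2 * F2)
  J <- a11 * a22
  # push-forward sigma = F S F' / J (per reference thickness)
  s11 <- (a11 * (S11 * a11 + S12 * a12) + a12 * (S12 * a11 + S22 * a12)) / J
  s12 <- (a11 * S12 * a22 + a12 * S22 * a22) / J
  s22 <- (a22 * S22 * a22) / J
  # current thickness from the 3D plane-stress thickness strain
  E3d <- material$E_matrix; nu <- material$nu_matrix
  lam3 <- E3d * nu / ((1 + nu) * (1 - 2 * nu)); mu3 <- E3d / (2 * (1 + nu))
  E33 <- -lam3 / (lam3 + 2 * mu3) * (st[, 10L] + st[, 11L])
  lam_t <- sqrt(pmax(1 + 2 * E33, 1e-6))
  s11 <- s11 / lam_t; s22 <- s22 / lam_t; s12 <- s12 / lam_t
  # eigen-decomposition of [[s11, s12], [s12, s22]]
  tr <- (s11 + s22) / 2
  dd <- sqrt(((s11 - s22) / 2)^2 + s12^2)
  sigma1 <- tr + dd; sigma2 <- tr - dd
  theta <- 0.5 * atan2(2 * s12, s11 - s22)
  ct <- cos(theta); sn <- sin(theta)
  dir1 <- t1 * ct + t2 * sn
  dir2 <- -t1 * sn + t2 * ct
  degenerate <- (sigma1 - sigma2) < 1e-6 * pmax(abs(sigma1), 1e-12)
  tri <- cache$tri0 + 1L
  centroid <- (X[tri[, 1L], , drop = FALSE] + X[tri[, 2L], , drop = FALSE] +
                 X[tri[, 3L], , drop = FALSE]) / 3
  structure(list(sigma1 = sigma1, sigma2 = sigma2, dir1 = dir1, dir2 = dir2,
                 degenerate = degenerate, area = mesh_areas(mesh, X),
                 centroid = centroid, cell = mesh$cell),
            class = "stress_field")
}

#' @export
print.stress_field <- function(x, ...) {
  cat("stress_field:", length(x$sigma1), "elements; sigma1 in [",
      signif(min(x$sigma1), 3), ",", signif(max(x$sigma1), 3), "] MPa;",
      sum(x$degenerate), "degenerate\n")
  invisible(x)
}

#' Iterate the stress-to-fiber feedback to a fixed point
#'
#' Solves the isotropic baseline, then repeatedly re-solves with each
#' element's fiber axis set to its previous maximal principal stress
#' direction, until the median per-element fiber rotation falls below
#' `tol_deg` degrees or `n_steps` is reached. If the median rotation fails
#' to decrease over 5 consecutive iterations the best iterate is returned
#' with a warning. Degenerate (near-isotropic) elements keep their previous
#' fiber.
#'
#' @param mesh template `surface_mesh` (beams attached).
#' @param material a [material_params()] object.
#' @param n_steps maximum feedback iterations.
#' @param tol_deg angular convergence tolerance (degrees).
#' @param loads optional load set; defaults to [apply_loads_and_bcs()].
#' @param control solver control list.
#' @return list: `mesh` (fibers updated), `stress` (final), `baseline`
#'   (isotropic stress field), `cosine` (per-element |cos| between final and
#'   baseline sigma1 directions), `angle_trace` (median rotation per
#'   iteration, degrees), `iterations`, `converged`, `displacements`.
#' @export
feedback_align <- function(mesh, material, n_steps = 12L, tol_deg = 1,
                           loads = NULL, control = list()) {
  if (is.null(loads)) loads <- apply_loads_and_bcs(mesh, material)
  T <- nrow(mesh$triangles)
  cache0 <- build_fem_cache(mesh, material, fiber = matrix(0, T, 3L))
  d0 <- solve_equilibrium(mesh, material, loads, control, cache = cache0)
  s0 <- principal_stress(d0, mesh, material)
  fib <- s0$dir1
  trace <- numeric(0)
  best <- NULL; best_med <- Inf
  Xw <- d0$X
  converged <- FALSE
  res <- NULL
  for (it in seq_len(n_steps)) {
    cache <- build_fem_cache(mesh, material, fiber = fib)
    d <- solve_equilibrium(mesh, material, loads, control, cache = cache,
                           init = Xw)
    s <- principal_stress(d, mesh, material)
    newfib <- s$dir1
    keep <- s$degenerate
    newfib[keep, ] <- fib[keep, , drop = FALSE]
    dt <- pmin(abs(rowSums(newfib * fib)), 1)
    med <- stats::median(acos(dt) * 180 / pi)
    trace <- c(trace, med)
    res <- list(fib = newfib, stress = s, disp = d)
    if (med < best_med) { best_med <- med; best <- res }
    fib <- newfib
    Xw <- d$X
    if (med < tol_deg) { converged <- TRUE; break }
    if (length(trace) >= 5L && all(diff(utils::tail(trace, 5L)) >= 0)) {
      warning("feedback alignment oscillating; returning best iterate")
      res <- best
      break
    }
  }
  mesh$fiber <- res$fib
  cosine <- pmin(abs(rowSums(res$stress$dir1 * s0$dir1)), 1)
  list(mesh = mesh, stress = res$stress, baseline = s0, cosine = cosine,
       angle_trace = trace, iterations = length(trace),
       converged = converged, displacements = res$disp)
}

#' Solve a (possibly perturbed) model
#'
#' Convenience wrapper combining the model's stiffness scales, per-cell
#' pressures and beam scales into one [solve_equilibrium()] call.
#'
#' @param model a [fem_model()] (possibly after [ablate()]).
#' @param control solver control list.
#' @param init optional warm-start coordinates.
#' @return a `fem_displacements` object.
#' @export
solve_model <- function(model, control = list(), init = NULL) {
  stopifnot(inherits(model, "fem_model"))
  loads <- apply_loads_and_bcs(model$mesh, model$material,
                               cell_pressure = model$cell_pressure)
  cache <- build_fem_cache(model$mesh, model$material,
                           stiffness_scale = model$stiffness_scale,
                           beam_scale = if (length(model$beam_scale))
                             model$beam_scale else NULL)
  solve_equilibrium(model$mesh, model$material, loads, control,
                    cache = cache, init = init)
}
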