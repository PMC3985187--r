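# Mechanical perturbations: cell ablation / large-scale laceration (turgor
# removed, wall softened), rigid-plate compression at constant enclosed
# volume, and the circumferential-alignment score used to read out the
# wound response.

#' Ablation specification
#'
#' Lacerated or laser-ablated cells lose turgor and their wall elasticity is
#' reduced. The softening factor is a free parameter of the model (0.1 by
#' default: mechanically passive, numerically well-conditioned).
#'
#' @param ablated_cells integer vector of cell labels to kill.
#' @param stiffness_factor multiplicative wall softening in (0, 1].
#' @return an `ablation_spec`.
#' @export
ablation_spec <- function(ablated_cells, stiffness_factor = 0.1) {
  stopifnot(stiffness_factor > 0, stiffness_factor <= 1)
  structure(list(ablated_cells = as.integer(ablated_cells),
                 stiffness_factor = stiffness_factor),
            class = "ablation_spec")
}

#' Ablate cells in a model
#'
#' Sets turgor to zero in the ablated cells and multiplies their element
#' stiffness by `stiffness_factor`. Beams whose incident cells are all
#' ablated are softened too; wound-edge beams (shared with a surviving cell)
#' keep full stiffness, since the survivor's anticlinal wall is intact.
#' An empty ablation set returns the model unchanged.
#'
#' @param model a [fem_model()].
#' @param spec an [ablation_spec()].
#' @return the modified model (attribute `wound` holds the wound boundary
#'   polyline when the mesh records cell-boundary segments).
#' @export
ablate <- function(model, spec) {
  stopifnot(inherits(model, "fem_model"), inherits(spec, "ablation_spec"))
  abl <- spec$ablated_cells
  if (!length(abl)) return(model)
  cells <- sort(unique(model$mesh$cell))
  if (!all(abl %in% cells)) stop("unknown cell label in ablation set")
  if (all(cells %in% abl)) stop("cannot ablate every cell: no load left")
  hit <- model$mesh$cell %in% abl
  model$stiffness_scale[hit] <- model$stiffness_scale[hit] * spec$stiffness_factor
  model$cell_pressure[as.character(abl)] <- 0
  if (!is.null(model$mesh$beams) && nrow(model$mesh$beams)) {
    b <- model$mesh$beams
    both <- b$cell_a %in% abl & (!is.na(b$cell_b) & b$cell_b %in% abl)
    model$beam_scale[both] <- model$beam_scale[both] * spec$stiffness_factor
  }
  attr(model, "wound") <- tryCatch(wound_boundary(model$mesh, abl),
                                   error = function(e) NULL)
  model
}

#' Wound boundary polyline around a set of ablated cells
#'
#' Chains the cell-boundary mesh segments separating ablated from surviving
#' tissue into a closed polyline (reference coordinates).
#'
#' @param mesh a template `surface_mesh` with `boundary_segments`.
#' @param cells ablated cell labels.
#' @return n x 2 matrix of polyline vertices (closed implicitly).
#' @export
wound_boundary <- function(mesh, cells) {
  segs <- mesh$boundary_segments
  if (is.null(segs)) stop("mesh has no recorded cell-boundary segments")
  ina <- segs$cell_a %in% cells
  inb <- !is.na(segs$cell_b) & segs$cell_b %in% cells
  sel <- xor(ina, inb)
  if (!any(sel)) stop("no wound boundary: ablated cells have no surviving neighbor")
  chain <- chain_boundary(data.frame(v1 = segs$v1[sel], v2 = segs$v2[sel]))
  mesh$vertices[chain, 1:2, drop = FALSE]
}

#' Circumferential alignment of maximal stress around a wound
#'
#' Area-weighted mean of cos^2 of the angle between each element's sigma1
#' direction (projected to the x-y plane) and the local wound tangent,
#' restricted to elements whose centroid lies outside the wound polygon
#' within `annulus = c(r_min, r_max)` of the wound boundary. 1 means
#' perfectly circumferential, 0 perfectly radial; random orientations give
#' 1/2 in expectation. Degenerate elements are excluded.
#'
#' @param stress a [principal_stress()] `stress_field`.
#' @param wound closed wound-boundary polyline (n x 2).
#' @param annulus numeric c(min, max) distance band (um).
#' @return scalar score in [0, 1].
#' @export
circumferential_alignment <- function(stress, wound, annulus) {
  stopifnot(inherits(stress, "stress_field"), is.matrix(wound),
            length(annulus) == 2L, annulus[2L] > annulus[1L])
  cen <- stress$centroid
  n <- nrow(cen)
  w <- numeric(0); c2 <- numeric(0)
  inside <- points_in_polygon(cen[, 1L], cen[, 2L], wound)
  for (e in seq_len(n)) {
    if (stress$degenerate[e] || inside[e]) next
    q <- dist_point_polyline(cen[e, 1:2], wound, closed = TRUE)
    if (q$dist < annulus[1L] || q$dist > annulus[2L]) next
    d1 <- stress$dir1[e, 1:2]
    nd <- sqrt(sum(d1^2))
    if (nd < 1e-9) next
    cosang <- sum(d1 / nd * q$tangent)
    w <- c(w, stress$area[e])
    c2 <- c(c2, cosang^2)
  }
  if (!length(w)) stop("empty annulus: no scorable elements in the band")
  sum(w * c2) / sum(w)
}

#' Compression specification
#'
#' @param plate_gap height of the rigid frictionless plate above the base
#'   plane (um, > 0).
#' @param friction must be 0 (only frictionless contact is modeled).
#' @param volume_constraint keep the enclosed volume within 1% of the
#'   unconfined pressurized volume by adjusting the internal pressure.
#' @return a `compression_spec`.
#' @export
compression_spec <- function(plate_gap, friction = 0, volume_constraint = TRUE) {
  if (plate_gap <= 0) stop("plate_gap must be positive")
  if (friction != 0) stop("only frictionless contact is supported")
  structure(list(plate_gap = plate_gap, friction = 0,
                 volume_constraint = isTRUE(volume_constraint)),
            class = "compression_spec")
}

#' Compress a closed pressurized surface with a rigid plate
#'
#' Solves the unconfined pressurized equilibrium first (its enclosed volume
#' is the conserved water volume), then lowers a frictionless rigid plane to
#' `plate_gap` (penalty contact on vertex height only, so tangential forces
#' vanish) and adjusts the internal pressure by secant iteration until the
#' enclosed volume matches the unconfined volume within 1%. A gap above the
#' free apex reproduces the unconfined solution.
#'
#' @param model a [fem_model()] whose mesh is closed (e.g. [make_cap_mesh()]).
#' @param spec a [compression_spec()].
#' @param control solver control list.
#' @return list: `displacements`, `stress` ([principal_stress()]),
#'   `pressure` (adjusted, MPa), `volume`, `volume0`, `contact` (logical per
#'   vertex).
#' @export
compress <- function(model, spec, control = list()) {
  stopifnot(inherits(model, "fem_model"), inherits(spec, "compression_spec"))
  mesh <- model$mesh
  if (!mesh$closed) stop("compression needs a closed pressurized surface")
  material <- model$material
  loads <- apply_loads_and_bcs(mesh, material,
                               cell_pressure = model$cell_pressure)
  cache <- build_fem_cache(mesh, material,
                           stiffness_scale = model$stiffness_scale)
  free0 <- solve_equilibrium(mesh, material, loads, control, cache = cache)
  V0 <- free0$volume
  kpen <- 50 * material$E_matrix * mean(mesh$thickness)
  solve_at <- function(P, init) {
    l2 <- loads
    l2$pressure <- rep(P, nrow(mesh$triangles))
    l2$contact <- list(gap = spec$plate_gap, k = kpen)
    solve_equilibrium(mesh, material, l2, control, cache = cache, init = init)
  }
  P0 <- max(model$cell_pressure)
  d1 <- solve_at(P0, free0$X)
  if (!spec$volume_constraint || abs(d1$volume - V0) / V0 <= 0.01) {
    res <- d1; P <- P0
  } else {
    P_a <- P0; V_a <- d1$volume
    P <- P0 * max(1.05, (V0 / V_a)^2)
    res <- NULL
    for (it in seq_len(15L)) {
      res <- solve_at(P, d1$X)
      if (abs(res$volume - V0) / V0 <= 0.005) break
      P_new <- P + (V0 - res$volume) * (P - P_a) / (res$volume - V_a)
      P_a <- P; V_a <- res$volume
      P <- max(P_new, 1e-4 * P0)
      if (it == 15L) stop("volume constraint infeasible at this plate gap")
    }
  }
  st <- principal_stress(res, mesh, material)
  list(displacements = res, stress = st, pressure = P,
       volume = res$volume, volume0 = V0,
       contact = res$X[, 3L] > spec$plate_gap - 1e-9)
}
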