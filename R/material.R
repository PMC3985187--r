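# Material and load parameters of the pavement-cell wall model.

#' Wall material and loading parameters
#'
#' Defaults follow the published pavement-cell model: matrix Young's modulus
#' 40 MPa, cellulose-microfibril reinforcement five times stiffer than the
#' matrix, turgor pressure 0.2 MPa, wall thickness 1 um, anticlinal beam
#' thickness 1/5 of the wall, and 1% in-plane pre-expansion of the template
#' boundary. The matrix Poisson ratio is not specified by the model source;
#' 0.3 is used (0.5 renders the plane-stress Saint Venant-Kirchhoff law
#' ill-conditioned).
#'
#' @param E_matrix matrix Young's modulus (MPa).
#' @param nu_matrix matrix Poisson ratio, in [0, 0.5).
#' @param fiber_ratio along-fiber to cross-fiber small-strain uniaxial
#'   stiffness ratio (>= 1; 1 disables the fiber term).
#' @param turgor_P turgor pressure (MPa).
#' @param wall_thickness periclinal wall thickness (um).
#' @param beam_fraction anticlinal beam thickness as a fraction of
#'   `wall_thickness`.
#' @param boundary_expansion in-plane radial pre-expansion of the template
#'   outer boundary (fraction).
#' @return a `material_params` list.
#' @export
material_params <- function(E_matrix = 40, nu_matrix = 0.3, fiber_ratio = 5,
                            turgor_P = 0.2, wall_thickness = 1,
                            beam_fraction = 1 / 5,
                            boundary_expansion = 0.01) {
  stopifnot(E_matrix > 0, nu_matrix >= 0, nu_matrix < 0.5, fiber_ratio >= 1,
            turgor_P >= 0, wall_thickness > 0, beam_fraction >= 0,
            boundary_expansion >= 0)
  structure(list(E_matrix = E_matrix, nu_matrix = nu_matrix,
                 fiber_ratio = fiber_ratio, turgor_P = turgor_P,
                 wall_thickness = wall_thickness,
                 beam_fraction = beam_fraction,
                 boundary_expansion = boundary_expansion),
            class = "material_params")
}

# plane-stress Lame coefficients
lame_plane_stress <- function(E, nu) {
  list(lambda = E * nu / (1 - nu^2), mu = E / (2 * (1 + nu)))
}

#' Fiber stiffness coefficient for a target anisotropy ratio
#'
#' The transversely isotropic augmentation `W_f = zeta/2 (a' E a)^2` is
#' calibrated so that the small-strain uniaxial (laterally free) stiffness
#' along the fiber is exactly `fiber_ratio` times the uniaxial stiffness
#' across it. Closed form: with plane-stress Lame coefficients and
#' `A = lambda + 2 mu`, `A + zeta` is the larger root of
#' `u^2 - (lambda^2/A + r A) u + r lambda^2 = 0`.
#'
#' @param material a [material_params()] object.
#' @return zeta (MPa); 0 when `fiber_ratio == 1`.
#' @export
fiber_zeta <- function(material) {
  r <- material$fiber_ratio
  if (r == 1) return(0)
  lp <- lame_plane_stress(material$E_matrix, material$nu_matrix)
  A <- lp$lambda + 2 * lp$mu
  b <- lp$lambda^2 / A + r * A
  u <- (b + sqrt(b^2 - 4 * r * lp$lambda^2)) / 2
  u - A
}
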