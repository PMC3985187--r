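# Reference (scalar) forms of the constitutive model. The finite-element
# kernels in src/ use the same formulas; these R versions are the documented
# surface and the target of the finite-difference consistency tests.

#' Green-Lagrange strain from a deformation gradient
#'
#' `E = (F'F - I)/2`. `F` may be k x k or 3 x 2 (membrane map from a 2D
#' reference tangent plane).
#'
#' @param F deformation gradient matrix with `det(F) > 0` (square case).
#' @return symmetric strain matrix of size `ncol(F)`.
#' @export
strain <- function(F) {
  F <- as.matrix(F)
  if (!all(is.finite(F))) stop("non-finite deformation gradient")
  if (nrow(F) == ncol(F) && det(F) <= 0)
    stop("deformation gradient must have positive determinant")
  (crossprod(F) - diag(ncol(F))) / 2
}

#' Saint Venant-Kirchhoff energy density and 2nd Piola-Kirchhoff stress
#'
#' Plane-stress reduction of the isotropic Saint Venant-Kirchhoff law:
#' `W = lambda/2 tr(E)^2 + mu tr(E^2)`, `S = lambda tr(E) I + 2 mu E`,
#' with the plane-stress Lame coefficients derived from
#' (`E_matrix`, `nu_matrix`).
#'
#' @param eps symmetric Green-Lagrange strain (2 x 2 for the membrane).
#' @param material a [material_params()] object.
#' @return list with `W` (MPa) and `S` (2nd PK stress, MPa).
#' @export
svk_energy <- function(eps, material) {
  eps <- as.matrix(eps)
  stopifnot(isTRUE(all.equal(eps, t(eps), tolerance = 1e-8)))
  lp <- lame_plane_stress(material$E_matrix, material$nu_matrix)
  tr <- sum(diag(eps))
  W <- lp$lambda / 2 * tr^2 + lp$mu * sum(eps * eps)
  S <- lp$lambda * tr * diag(nrow(eps)) + 2 * lp$mu * eps
  list(W = W, S = S)
}

#' Transversely isotropic fiber augmentation
#'
#' `W_f = zeta/2 (a' E a)^2` with stress contribution
#' `S_f = zeta (a' E a) a a'`; `zeta` comes from [fiber_zeta()] so the
#' along/cross uniaxial stiffness ratio equals `material$fiber_ratio`.
#'
#' @param eps symmetric strain matrix (2 x 2).
#' @param a fiber direction (length-2); normalized with a warning if not
#'   unit-length.
#' @param material a [material_params()] object.
#' @return list with `W`, `S`.
#' @export
fiber_energy <- function(eps, a, material) {
  eps <- as.matrix(eps)
  a <- as.numeric(a)
  stopifnot(length(a) == nrow(eps))
  na <- sqrt(sum(a^2))
  if (na == 0) stop("fiber direction must be non-zero")
  if (abs(na - 1) > 1e-8) {
    warning("fiber direction not unit-length; normalizing")
    a <- a / na
  }
  ze <- fiber_zeta(material)
  q <- as.numeric(t(a) %*% eps %*% a)
  list(W = ze / 2 * q^2, S = ze * q * (a %o% a))
}
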