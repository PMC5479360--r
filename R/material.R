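# Reduced Holzapfel-Ogden constitutive law: transversely isotropic exponential
# strain energy with isotropic (a, b) and fibre (a_f, b_f) terms,
#   Psi = a/(2b) (exp(b (II_F - 3)) - 1) + a_f/(2 b_f) (exp(b_f (II_Ff - 1)^2) - 1)
# with II_F = F : F and II_Ff = F f0 . F f0.

#' Material parameters of the reduced Holzapfel-Ogden law
#'
#' The exponents b and b_f are kept fixed (default 5) so that the stiffness
#' scales (a, a_f) remain comparable across cases; they are not estimated.
#'
#' @param a isotropic stiffness scale (Pa), > 0.
#' @param a_f fibre stiffness scale (Pa), >= 0.
#' @param b,b_f dimensionless exponents, > 0.
#' @param kappa_rel dimensionless augmented-Lagrangian penalty used by the
#'   solver on top of the pressure multiplier to control pointwise volume
#'   change at quadrature points; the absolute penalty is
#'   `kappa_rel * max(a_f, a)` Pa so that joint scaling of (a, a_f) scales
#'   every term of the energy identically.
#' @return object of class `lv_material`.
#' @export
material_parameters <- function(a, a_f, b = 5, b_f = 5, kappa_rel = 3000) {
  if (!is.finite(a) || a <= 0) stop("a must be positive")
  if (!is.finite(a_f) || a_f < 0) stop("a_f must be non-negative")
  if (b <= 0 || b_f <= 0) stop("exponents b, b_f must be positive")
  if (kappa_rel < 0) stop("kappa_rel must be non-negative")
  structure(list(a = a, b = b, a_f = a_f, b_f = b_f,
                 kappa = kappa_rel * max(a_f, a)), class = "lv_material")
}

#' Strain-energy density of the reduced Holzapfel-Ogden law
#'
#' @param F 3x3 deformation gradient with det F > 0.
#' @param f0 unit fibre direction in the reference configuration.
#' @param params an [material_parameters()] object.
#' @return energy density in Pa (J / m^3).
#' @export
strain_energy_density <- function(F, f0, params) {
  if (!all(is.finite(F))) stop("non-finite deformation gradient")
  if (det(F) <= 0) stop("det F must be positive")
  stopifnot(abs(sum(f0^2) - 1) < 1e-8)
  IIF <- sum(F * F)
  h <- as.vector(F %*% f0)
  kap <- sum(h^2)
  with(params,
       a / (2 * b) * (exp(b * (IIF - 3)) - 1) +
       a_f / (2 * b_f) * (exp(b_f * (kap - 1)^2) - 1))
}

#' First Piola-Kirchhoff stress
#'
#' P = dPsi/dF + p J F^-T for the incompressible formulation; the associated
#' Cauchy stress (1/J) P F^T is symmetric.
#'
#' @inheritParams strain_energy_density
#' @param p hydrostatic pressure (Pa).
#' @return 3x3 stress tensor (Pa).
#' @export
first_piola_stress <- function(F, f0, params, p = 0) {
  if (!all(is.finite(F))) stop("non-finite deformation gradient")
  J <- det(F)
  if (abs(J) < .Machine$double.eps) stop("singular deformation gradient")
  IIF <- sum(F * F)
  h <- as.vector(F %*% f0)
  kap <- sum(h^2)
  with(params,
       a * exp(b * (IIF - 3)) * F +
       2 * a_f * (kap - 1) * exp(b_f * (kap - 1)^2) * (h %o% f0) +
       p * J * t(solve(F)))
}
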