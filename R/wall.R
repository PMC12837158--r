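#' Orthotropic aortic-wall material
#'
#' The aortic wall is stiffer longitudinally than circumferentially because of
#' the orientation of its collagen and elastin fibres; an orthotropic linear
#' description captures this with two elastic moduli, a shear modulus and a
#' Poisson ratio. No consensus numeric values exist for these constants, so
#' the defaults are placeholder magnitudes of the right order for aortic
#' tissue and should be overridden from the case configuration when known.
#'
#' @param E_L longitudinal elastic modulus (MPa).
#' @param E_C circumferential elastic modulus (MPa).
#' @param G_LC in-plane shear modulus (MPa).
#' @param v_LC Poisson's ratio (dimensionless, in \[0, 0.5)).
#' @return an object of class `orthotropic_material`.
#' @examples
#' mat <- orthotropic_material(E_L = 2, E_C = 1, G_LC = 0.5, v_LC = 0.3)
#' elastic_modulus_at_angle(mat, c(0, pi / 4, pi / 2))
#' @export
orthotropic_material <- function(E_L = 3.0, E_C = 1.5, G_LC = 0.6,
                                 v_LC = 0.27) {
  if (E_L <= 0 || E_C <= 0 || G_LC <= 0)
    stop("elastic and shear moduli must be positive")
  if (v_LC < 0 || v_LC >= 0.5)
    stop("Poisson's ratio must lie in [0, 0.5)")
  structure(list(E_L = E_L, E_C = E_C, G_LC = G_LC, v_LC = v_LC),
            class = "orthotropic_material")
}

#' @export
print.orthotropic_material <- function(x, ...) {
  cat(sprintf(
    "orthotropic_material: E_L = %.3g, E_C = %.3g, G_LC = %.3g MPa, v_LC = %.3g\n",
    x$E_L, x$E_C, x$G_LC, x$v_LC))
  invisible(x)
}

#' Directional elastic modulus of an orthotropic wall
#'
#' Evaluates the compliance transformation
#' \deqn{1/E_\theta = \cos^4\theta/E_L + \sin^4\theta/E_C +
#'   \tfrac14\left(1/G_{LC} - 2\nu_{LC}/E_L\right)\sin^2(2\theta)}
#' giving the apparent elastic modulus at angle `theta` from the longitudinal
#' direction. `E_0 = E_L`, `E_{pi/2} = E_C`, and the function has period pi.
#'
#' @param mat an [orthotropic_material()].
#' @param theta angle(s) from the longitudinal direction, radians.
#' @return modulus E_theta in MPa, same length as `theta`.
#' @export
elastic_modulus_at_angle <- function(mat, theta) {
  stopifnot(inherits(mat, "orthotropic_material"))
  ct <- cos(theta)
  st <- sin(theta)
  inv <- ct^4 / mat$E_L + st^4 / mat$E_C +
    0.25 * (1 / mat$G_LC - 2 * mat$v_LC / mat$E_L) * sin(2 * theta)^2
  1 / inv
}
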