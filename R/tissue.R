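# Tissue composition and derived material quantities.
#
# A material point is described by the bone volume fraction vb (bone tissue
# per total volume, pores included) and by the composition of the tissue
# itself: mineral (vm), organic (vo, constant) and water (vw) volume
# fractions, with vm + vo + vw = 1.  Secondary mineralization replaces water
# with mineral, so vm alone fixes the tissue composition.

#' Tissue-phase constants
#'
#' Densities of the mineral, organic and water phases of bone tissue and the
#' (constant) organic volume fraction.  The defaults are the values used
#' throughout the bone-remodeling literature for human bone.
#'
#' @param rho_m mineral phase density, g/cm^3.
#' @param rho_o organic phase density, g/cm^3.
#' @param rho_w water density, g/cm^3.
#' @param v_o organic volume fraction of bone tissue (dimensionless).
#' @return A list of class `tissue_constants`.
#' @export
#' @examples
#' tc <- tissue_constants()
#' ash_fraction(0.3, tc)
tissue_constants <- function(rho_m = 3.2, rho_o = 1.1, rho_w = 1.0, v_o = 3 / 7) {
  stopifnot(rho_m > rho_o, rho_o > rho_w, rho_w > 0, v_o > 0, v_o < 1)
  structure(list(rho_m = rho_m, rho_o = rho_o, rho_w = rho_w, v_o = v_o),
            class = "tissue_constants")
}

#' Water volume fraction of bone tissue
#'
#' Water fills whatever tissue volume is not occupied by mineral or organic
#' matrix: `v_w = 1 - v_o - v_m`.  As the tissue mineralizes, mineral
#' replaces water.
#'
#' @param v_m mineral volume fraction of bone tissue, in `[0, 1 - v_o]`.
#' @param tc a [tissue_constants()] object.
#' @return Water volume fraction (same length as `v_m`).
#' @export
water_fraction <- function(v_m, tc = tissue_constants()) {
  v_m <- .clamp_fraction(v_m, "v_m", 0, 1 - tc$v_o)
  1 - tc$v_o - v_m
}

#' Ash fraction from mineral volume fraction
#'
#' The ash fraction is the mineral mass over the dry (mineral + organic)
#' mass of the tissue: `alpha = rho_m v_m / (rho_m v_m + rho_o v_o)`.
#' It is the standard compositional proxy for tissue age.
#'
#' @inheritParams water_fraction
#' @return Ash fraction in `[0, 1)`.
#' @export
ash_fraction <- function(v_m, tc = tissue_constants()) {
  v_m <- .clamp_fraction(v_m, "v_m", 0, 1 - tc$v_o)
  tc$rho_m * v_m / (tc$rho_m * v_m + tc$rho_o * tc$v_o)
}

#' Mineral volume fraction from ash fraction
#'
#' Inverse of [ash_fraction()]: `v_m = rho_o v_o alpha / (rho_m (1 - alpha))`.
#' Used to initialize tissue layers from a target ash fraction.
#'
#' @param alpha ash fraction in `[0, 1)`.
#' @inheritParams water_fraction
#' @return Mineral volume fraction.
#' @export
mineral_fraction_from_ash <- function(alpha, tc = tissue_constants()) {
  if (any(!is.finite(alpha)) || any(alpha < -1e-12) || any(alpha >= 1)) {
    stop("alpha must lie in [0, 1)", call. = FALSE)
  }
  alpha <- pmax(alpha, 0)
  tc$rho_o * tc$v_o * alpha / (tc$rho_m * (1 - alpha))
}

#' Elastic modulus of bone
#'
#' Power-law stiffness of bone as a function of bone volume fraction and
#' ash fraction, `E = 84370 vb^2.58 alpha^2.74` MPa, the isotropic
#' composition-to-stiffness relation calibrated on human bone.
#'
#' @param v_b bone volume fraction in `[0, 1]`.
#' @param alpha ash fraction in `[0, 1]`.
#' @return Elastic modulus, MPa.
#' @export
#' @examples
#' elastic_modulus(1, 1)     # 84370 MPa: the coefficient itself
#' elastic_modulus(0.5, 0.7)
elastic_modulus <- function(v_b, alpha) {
  v_b <- .clamp_fraction(v_b, "v_b")
  alpha <- .clamp_fraction(alpha, "alpha")
  84370 * v_b^2.58 * alpha^2.74
}

#' Bone mineral density
#'
#' Volumetric mineral mass per unit total volume, `BMD = rho_m v_m v_b`
#' (g/cm^3), the model counterpart of a densitometric BMD measurement.
#'
#' @param v_b bone volume fraction.
#' @param v_m mineral volume fraction of bone tissue.
#' @inheritParams water_fraction
#' @return BMD, g/cm^3.
#' @export
bone_mineral_density <- function(v_b, v_m, tc = tissue_constants()) {
  v_b <- .clamp_fraction(v_b, "v_b")
  v_m <- .clamp_fraction(v_m, "v_m")
  tc$rho_m * v_m * v_b
}

#' Material density of bone tissue
#'
#' Mass of bone tissue per unit tissue volume (pores excluded):
#' `rho_mat = rho_m v_m + rho_o v_o + rho_w v_w`, with the water fraction
#' given by [water_fraction()].  Driven by mineralization.
#'
#' @inheritParams water_fraction
#' @return Material density, g/cm^3.
#' @export
material_density <- function(v_m, tc = tissue_constants()) {
  v_w <- water_fraction(v_m, tc)
  v_m <- pmin(pmax(v_m, 0), 1 - tc$v_o)
  tc$rho_m * v_m + tc$rho_o * tc$v_o + tc$rho_w * v_w
}

#' Apparent density of bone
#'
#' Mass of bone tissue per unit total volume (pores included):
#' `rho_app = rho_mat v_b`.  Driven by porosity.
#'
#' @param rho_mat material density, g/cm^3.
#' @param v_b bone volume fraction.
#' @return Apparent density, g/cm^3.
#' @export
apparent_density <- function(rho_mat, v_b) {
  stopifnot(all(rho_mat >= 0))
  v_b <- .clamp_fraction(v_b, "v_b")
  rho_mat * v_b
}

#' Specific surface of bone as a function of porosity
#'
#' Free bone surface area per unit volume, on which BMUs originate.  The
#' default curve is Martin's quintic
#' `Sv(p) = 32.3 p - 93.9 p^2 + 134 p^3 - 101 p^4 + 28.8 p^5` (1/mm):
#' zero in solid bone, small again at very high porosity, and maximal in the
#' cortical-trabecular transition zone, which is why transitional tissue
#' remodels fastest.  Alternative polynomial coefficients (ascending powers,
#' no intercept) may be supplied.
#'
#' @param porosity pore volume fraction `1 - v_b`, in `[0, 1]`.
#' @param coef polynomial coefficients of `p, p^2, ...` (1/mm).
#' @return Specific surface, 1/mm (negative polynomial excursions are
#'   clamped to zero).
#' @export
#' @examples
#' specific_surface(c(0.05, 0.4, 0.8))
specific_surface <- function(porosity,
                             coef = c(32.3, -93.9, 134, -101, 28.8)) {
  porosity <- .clamp_fraction(porosity, "porosity")
  out <- rep(0, length(porosity))
  for (k in rev(seq_along(coef))) out <- (out + coef[k]) * porosity
  pmax(out, 0)
}
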