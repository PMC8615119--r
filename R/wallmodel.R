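#' Aneurysmal wall geometry
#'
#' Idealised curved-tube description of the ascending aortic wall used by
#' the analytic stress surrogate and the synthetic mesh generator.
#' Defaults describe the study case: 54 mm outer diameter, 2.1 mm wall,
#' 105 mm ascending length, 8.2 mm systolic root displacement and a
#' ventricular traction force cycling between 1.28 N (relaxation) and
#' 1.92 N (peak contraction).
#'
#' @param outer_diameter Outer diameter (mm).
#' @param thickness Wall thickness (mm); must be positive and smaller than
#'   the outer radius.
#' @param ascending_length Ascending centerline length (mm).
#' @param centerline_curvature Arc curvature of the centerline (1/mm).
#' @param root_displacement Systolic downward root displacement (mm).
#' @param traction_force_max,traction_force_min Ventricular traction force
#'   at peak contraction / relaxation (N).
#' @return An object of class `wall_geometry`.
#' @export
wall_geometry <- function(outer_diameter = 54, thickness = 2.1,
                          ascending_length = 105,
                          centerline_curvature = 1 / 80,
                          root_displacement = 8.2,
                          traction_force_max = 1.92,
                          traction_force_min = 1.28) {
  if (thickness <= 0 || thickness >= outer_diameter / 2) {
    stop("thickness must be positive and smaller than the outer radius",
         call. = FALSE)
  }
  if (outer_diameter <= 0 || ascending_length <= 0 || centerline_curvature <= 0) {
    stop("geometry dimensions must be positive", call. = FALSE)
  }
  structure(list(outer_diameter = outer_diameter, thickness = thickness,
                 ascending_length = ascending_length,
                 centerline_curvature = centerline_curvature,
                 root_displacement = root_displacement,
                 traction_force_max = traction_force_max,
                 traction_force_min = traction_force_min),
            class = "wall_geometry")
}

# mid-wall radius (mm)
wall_mid_radius <- function(geom) geom$outer_diameter / 2 - geom$thickness / 2

#' Thin-wall (Laplace) membrane stresses
#'
#' Closed-form membrane baseline for a pressurised thin-walled tube:
#' circumferential stress `S_C = p r / t` and longitudinal (closed-end)
#' stress `S_L = p r / (2 t)` at the mid-wall radius, in kPa. The
#' circumferential component is exactly twice the longitudinal one.
#'
#' @param geom A [wall_geometry()].
#' @param pressure Luminal pressure (mmHg).
#' @return A one-row tibble with `S_C`, `S_L` (kPa). Warns (but still
#'   computes) outside the thin-wall regime `t/r < 0.2`.
#' @examples
#' laplace_stress(wall_geometry(), 132)
#' @export
laplace_stress <- function(geom, pressure) {
  r <- wall_mid_radius(geom)
  if (geom$thickness / r >= 0.2) {
    warning("thick-wall geometry (t/r >= 0.2): thin-wall formulas are approximate")
  }
  p_kpa <- pressure * MMHG_TO_KPA
  tibble::tibble(S_C = p_kpa * r / geom$thickness,
                 S_L = p_kpa * r / (2 * geom$thickness))
}

#' Longitudinal stress under pressure, traction and arc bending
#'
#' Analytic surrogate for the longitudinal wall stress of the ascending
#' aneurysm under three superposed loads: the closed-end membrane term
#' `p r/(2t)`, a uniform axial traction term `F/(2 pi r t)` from the
#' systolic downward pull of the ventricle, and a through-thickness bending
#' term from the arc-shaped vessel straightening under tension. The bending
#' couple `M = F x moment_arm` produces `+/- M r cos(theta - theta_M) / I`
#' with `I = pi r^3 t`: tensile on the inner surface and compressive on the
#' outer surface where the moment acts (the transmural sign-change
#' mechanism), with `theta_M` at the major curvature by default.
#'
#' @param geom A [wall_geometry()].
#' @param pressure Luminal pressure (mmHg).
#' @param axial_force Ventricular traction force (N).
#' @param moment_arm Effective lever arm of the traction force about the
#'   tethered distal end (mm); `M = axial_force * moment_arm`.
#' @param theta Angular stations (degrees); default every 5 degrees.
#' @param moment_axis_deg Angle of maximum bending tension (degrees);
#'   default 270 (the major-curvature quadrant).
#' @return A tibble with columns `theta`, `surface` (`"inner"`/`"outer"`)
#'   and `S_L` (kPa), one row per station per surface.
#' @export
traction_bending_stress <- function(geom, pressure, axial_force, moment_arm,
                                    theta = seq(0, 355, by = 5),
                                    moment_axis_deg = 270) {
  if (geom$thickness <= 0) stop("zero wall thickness", call. = FALSE)
  r <- wall_mid_radius(geom)
  t <- geom$thickness
  memb <- laplace_stress(geom, pressure)$S_L                 # kPa
  tract <- axial_force / (2 * pi * r * t) * 1000             # N/mm^2 -> kPa
  I <- pi * r^3 * t                                          # mm^4
  M <- axial_force * moment_arm                              # N.mm
  bend <- M * r / I * 1000 * cos((theta - moment_axis_deg) * pi / 180)  # kPa
  out <- tidyr::expand_grid(theta = theta, surface = c("inner", "outer"))
  sgn <- ifelse(out$surface == "inner", 1, -1)
  out$S_L <- memb + tract + sgn * bend[match(out$theta, theta)]
  out
}
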