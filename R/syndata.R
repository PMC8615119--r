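#' Generate a synthetic equibiaxial dataset
#'
#' Emulates a displacement-controlled planar equibiaxial test: a uniform
#' engineering-strain ramp with equal stretch in both in-plane directions,
#' stresses evaluated from the analytic constitutive model, then corrupted
#' by multiplicative lognormal noise (heteroscedastic, as soft-tissue
#' stress data are) with the requested coefficient of variation.
#' Deterministic under a fixed seed.
#'
#' @param params Generating [ho_params()].
#' @param arch Fiber architecture; default 34 degrees.
#' @param n_points Number of samples along the ramp (>= 5); default 30.
#' @param max_eng_strain Ramp endpoint (engineering strain); default 0.18.
#' @param noise_cv Coefficient of variation of the multiplicative noise;
#'   default 0.02; 0 gives the exact analytic stresses.
#' @param seed Integer seed.
#' @return A [biaxial_dataset()].
#' @examples
#' gen_biaxial(ataa_params(), seed = 42)
#' @export
gen_biaxial <- function(params, arch = fiber_architecture(34), n_points = 30,
                        max_eng_strain = 0.18, noise_cv = 0.02, seed = 1L) {
  if (n_points < 5) stop("n_points must be at least 5", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  eng <- seq(0, max_eng_strain, length.out = n_points)
  lam <- 1 + eng
  pk <- first_pk_stress(deformation_state(lam, lam), params, arch)
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    fac <- with_seed(seed, matrix(
      stats::rlnorm(2 * n_points, meanlog = -sdlog^2 / 2, sdlog = sdlog),
      ncol = 2))
    pk$P_circ <- pk$P_circ * fac[, 1]
    pk$P_long <- pk$P_long * fac[, 2]
  }
  biaxial_dataset(E_circ = strain_convert(eng), E_long = strain_convert(eng),
                  P_circ = pk$P_circ, P_long = pk$P_long)
}

#' The study patient's clinical record
#'
#' Returns the fixed single-patient record driving the circulation
#' calibration: cuff pressures 132/84 mmHg with MAP 102 mmHg, stroke volume
#' 64 mL, cardiac output 4.9 L/min, heart rate 60 bpm and a 414 mm^2
#' tri-leaflet aortic valve orifice.
#'
#' @return A [clinical_record()].
#' @examples
#' gen_patient_record()
#' @export
gen_patient_record <- function() {
  clinical_record(sbp = 132, dbp = 84, map = 102, sv = 64, co = 4.9, hr = 60,
                  valve_orifice_area = 414)
}

#' Generate a synthetic curved-tube wall mesh with stress fields
#'
#' Builds the inner and outer surface point clouds of an idealised curved
#' tube (a torus segment standing in for the ascending aorta), evaluates
#' the surrogate stresses on it - uniform Laplace circumferential stress
#' and the pressure + traction + arc-bending longitudinal field, whose
#' maximum sits on the major curvature - and optionally corrupts both
#' components with seeded multiplicative lognormal noise.
#'
#' @param geom A [wall_geometry()].
#' @param n_axial Number of axial rings (>= 8); default 40.
#' @param n_circ Number of circumferential stations (>= 8); default 36.
#' @param pressure Luminal pressure (mmHg); default 132.
#' @param force Ventricular traction force (N); default 1.92.
#' @param arm Bending moment arm (mm); default 0 (no bending).
#' @param phase Phase label; default `"systole"`.
#' @param noise_cv Multiplicative noise CV; default 0.
#' @param seed Integer seed.
#' @return A [stress_field()] tibble with embedded coordinates `x`, `y`,
#'   `z` (mm), ready for [write_stress_vtk()].
#' @export
gen_wall_mesh <- function(geom = wall_geometry(), n_axial = 40, n_circ = 36,
                          pressure = 132, force = 1.92, arm = 0,
                          phase = "systole", noise_cv = 0, seed = 1L) {
  if (n_axial < 8 || n_circ < 8) {
    stop("need at least 8 axial rings and 8 circumferential stations",
         call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  s <- seq(0, 1, length.out = n_axial)
  theta <- seq(0, 360 - 360 / n_circ, by = 360 / n_circ)
  r_out <- geom$outer_diameter / 2
  r_in <- r_out - geom$thickness
  Rc <- 1 / geom$centerline_curvature
  phi_max <- geom$ascending_length * geom$centerline_curvature

  grid <- tidyr::expand_grid(s = s, theta = theta,
                             surface = c("inner", "outer"))
  phi <- grid$s * phi_max
  th <- grid$theta * pi / 180
  r_surf <- ifelse(grid$surface == "inner", r_in, r_out)
  # centerline arc in the x-z plane; u_out points away from the arc center
  # (the major-curvature side, theta = 270), u_ant is the binormal (theta = 0)
  cx <- Rc * sin(phi); cz <- Rc * (1 - cos(phi))
  ux_out <- sin(phi); uz_out <- -cos(phi)
  d_out <- -sin(th)                 # component along u_out
  d_ant <- cos(th)                  # component along the binormal (y)
  grid$x <- cx + r_surf * d_out * ux_out
  grid$y <- r_surf * d_ant
  grid$z <- cz + r_surf * d_out * uz_out

  sc <- laplace_stress(geom, pressure)$S_C
  sl <- traction_bending_stress(geom, pressure, force, arm, theta = theta)
  grid <- dplyr::left_join(grid, sl, by = c("theta", "surface"))
  grid$S_C <- sc
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    fac <- with_seed(seed, matrix(
      stats::rlnorm(2 * nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog),
      ncol = 2))
    grid$S_C <- grid$S_C * fac[, 1]
    grid$S_L <- grid$S_L * fac[, 2]
  }
  grid$phase <- phase
  stress_field(grid)
}
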