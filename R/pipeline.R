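#' Pipeline run configuration
#'
#' Assembles the full configuration of an end-to-end run: every seed is
#' explicit, and the whole object round-trips through JSON, so two runs
#' with the same config are identical.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Master seed; stage seeds default to small fixed offsets of it.
#' @param biaxial_csv Optional path to an existing biaxial CSV; when `NULL`
#'   a synthetic dataset is generated from `true_params`.
#' @param true_params Generating [ho_params()] for the synthetic biaxial
#'   stage; default [ataa_params()].
#' @param fiber_angle Fiber angle in degrees; default 34.
#' @param n_points,noise_cv Synthetic biaxial ramp size and noise level.
#' @param strain_cutoff Engineering-strain validity window; default 0.18.
#' @param pressure_tol Cuff-pressure refinement tolerance (mmHg); default 1.
#' @param moment_arm Surrogate bending moment arm (mm).
#' @param s_levels Section arclength levels; default `c(0.05, 0.5, 0.9)`.
#' @param n_axial,n_circ Wall-mesh resolution.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("ataamech_run_"), seed = 1L,
                       biaxial_csv = NULL, true_params = ataa_params(),
                       fiber_angle = 34, n_points = 30, noise_cv = 0.02,
                       strain_cutoff = 0.18, pressure_tol = 1,
                       moment_arm = 300, s_levels = c(0.05, 0.5, 0.9),
                       n_axial = 40, n_circ = 36) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 biaxial_csv = biaxial_csv,
                 true_params = unclass(true_params),
                 fiber_angle = fiber_angle, n_points = n_points,
                 noise_cv = noise_cv, strain_cutoff = strain_cutoff,
                 pressure_tol = pressure_tol, moment_arm = moment_arm,
                 s_levels = s_levels, n_axial = n_axial, n_circ = n_circ),
            class = "run_config")
}

#' Run the whole patient-specific pipeline
#'
#' Executes the stages in order - synthetic biaxial generation (or CSV
#' ingest), constitutive fit, circulation calibration and refinement,
#' surrogate wall-stress mesh, quadrant post-processing - writing each
#' stage's artifact under `config$out_dir` plus a JSON manifest recording
#' the config, the seeds, the per-stage outputs and a metric summary. A
#' stage failure is recorded in the manifest (`status = "failed"`,
#' `failed_stage`, `error`) rather than thrown.
#'
#' @param config A [run_config()].
#' @return The manifest (a list), invisibly; also written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  manifest <- list(config = unclass(config), stages = list(),
                   status = "ok", metrics = list())
  arch <- fiber_architecture(config$fiber_angle)

  run_stage <- function(name, expr) {
    res <- tryCatch(list(value = force(expr), error = NULL),
                    error = function(e) list(value = NULL,
                                             error = conditionMessage(e)))
    if (is.null(res$error)) {
      manifest$stages[[name]] <<- list(status = "ok")
    } else {
      manifest$stages[[name]] <<- list(status = "failed", error = res$error)
      manifest$status <<- "failed"
      manifest$failed_stage <<- name
    }
    res$value
  }

  finish <- function() {
    writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                             digits = NA, null = "null")),
               path("manifest.json"))
    invisible(manifest)
  }

  # stage 1: biaxial data (synthesise unless a CSV is supplied)
  csv <- run_stage("biaxial_data", {
    if (is.null(config$biaxial_csv)) {
      ds <- gen_biaxial(do.call(ho_params, config$true_params), arch,
                        n_points = config$n_points,
                        max_eng_strain = config$strain_cutoff,
                        noise_cv = config$noise_cv, seed = config$seed)
      write_biaxial_csv(ds, path("biaxial.csv"))
      path("biaxial.csv")
    } else config$biaxial_csv
  })
  if (manifest$status == "failed") return(finish())

  # stage 2: constitutive fit
  fit <- run_stage("fit", {
    ds <- read_biaxial_csv(csv) |> truncate_to_window(config$strain_cutoff)
    f <- fit_ho(ds, seed = config$seed + 1L, arch = arch)
    fit_to_json(f, path("fit.json"))
    f
  })
  if (manifest$status == "failed") return(finish())
  manifest$metrics$fit <- list(params = unclass(fit$params), r = fit$r,
                               nrmse = fit$nrmse)

  # stage 3: circulation
  sim <- run_stage("circulation", {
    rec <- gen_patient_record()
    write_record_json(rec, path("record.json"))
    p0 <- calibrate(rec)
    p1 <- refine_to_cuff(p0, rec, tol = config$pressure_tol)
    s <- simulate_circulation(p1)
    write_trace_csv(s, path("trace.csv"))
    s
  })
  if (manifest$status == "failed") return(finish())
  pv <- pv_metrics(sim, bsa = 1.9)
  manifest$metrics$circulation <- as.list(pv)

  # stage 4: surrogate wall-stress mesh at systolic pressure
  field <- run_stage("wall_mesh", {
    geom <- wall_geometry()
    fld <- gen_wall_mesh(geom, n_axial = config$n_axial,
                         n_circ = config$n_circ,
                         pressure = sim$metrics$SBP,
                         force = geom$traction_force_max,
                         arm = config$moment_arm, seed = config$seed + 2L)
    write_stress_vtk(fld, path("wall_systole.vtk"))
    fld
  })
  if (manifest$status == "failed") return(finish())

  # stage 5: quadrant post-processing
  qs <- run_stage("quadrants", {
    q <- read_stress_vtk(path("wall_systole.vtk")) |>
      extract_sections(s_levels = config$s_levels) |>
      quadrant_summary()
    write_quadrant_csv(q, path("quadrants.csv"))
    write_quadrant_csv(transmural_delta(q), path("transmural.csv"))
    q
  })
  if (manifest$status == "failed") return(finish())
  delta <- transmural_delta(qs)
  manifest$metrics$quadrants <- list(
    n_rows = nrow(qs),
    n_sign_change_S_L = sum(delta$sign_change_S_L)
  )
  finish()
}
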