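#' Stress field on a wall mesh
#'
#' Validates and labels a point cloud of wall-stress samples. Each point
#' carries a normalised centerline arclength coordinate `s` in `[0, 1]`, an
#' angular coordinate `theta` in `[0, 360)` degrees (0 = anterior,
#' increasing toward the patient's right: 90 = minor curvature,
#' 180 = posterior, 270 = major curvature), a `surface` label
#' (`"inner"`/`"outer"`), the stress components `S_C` and `S_L` in kPa and
#' a cardiac `phase` label (`"systole"`/`"diastole"`).
#'
#' @param df A data frame with columns `s`, `theta`, `surface`, `S_C`,
#'   `S_L` and optionally `phase` (default `"systole"`).
#' @return A tibble of class `stress_field`.
#' @export
stress_field <- function(df) {
  need <- c("s", "theta", "surface", "S_C", "S_L")
  if (!all(need %in% names(df))) {
    stop("stress field needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  if (!"phase" %in% names(out)) out$phase <- "systole"
  if (any(!is.finite(out$S_C)) || any(!is.finite(out$S_L))) {
    stop("stress components must be finite", call. = FALSE)
  }
  if (any(out$s < 0 | out$s > 1)) {
    stop("arclength coordinate s must lie in [0, 1]", call. = FALSE)
  }
  if (!all(out$surface %in% c("inner", "outer"))) {
    stop("surface labels must be 'inner' or 'outer'", call. = FALSE)
  }
  out$theta <- out$theta %% 360
  class(out) <- unique(c("stress_field", class(out)))
  out
}

#' Extract anatomical cross-sections from a stress field
#'
#' Tags the points lying within an arclength band around each of three
#' anatomical levels: section A near the sino-tubular junction, B at the
#' mid-ascending aorta, C just before the brachiocephalic trunk.
#'
#' @param field A [stress_field()].
#' @param s_levels Three arclength fractions; default `c(0.05, 0.50, 0.90)`.
#' @param band Half-width of each band in arclength fraction; default 0.025
#'   (bands are clipped to `[0, 1]` at the domain boundary).
#' @return The field restricted to the bands, with a `section` column
#'   (`"A"`, `"B"`, `"C"`). Errors if any band contains no points, naming
#'   the offending level.
#' @export
extract_sections <- function(field, s_levels = c(0.05, 0.50, 0.90),
                             band = 0.025) {
  stopifnot(length(s_levels) == 3)
  labels <- c("A", "B", "C")
  parts <- purrr::map2(s_levels, labels, function(level, lab) {
    lo <- max(level - band, 0)
    hi <- min(level + band, 1)
    part <- dplyr::filter(field, .data$s >= lo, .data$s <= hi)
    if (nrow(part) == 0) {
      stop(sprintf("no mesh points within %.3g of arclength level %.3g (section %s)",
                   band, level, lab), call. = FALSE)
    }
    part$section <- lab
    part
  })
  out <- dplyr::bind_rows(parts)
  class(out) <- unique(c("stress_field", class(out)))
  out
}

#' Quadrant index of an angular coordinate
#'
#' Quadrant `k` spans `[45(k-1) - 22.5, 45(k-1) + 22.5)` degrees, so the
#' quadrant centers sit on the anatomical directions: 1 = anterior,
#' 3 = minor curvature, 5 = posterior, 7 = major curvature.
#'
#' @param theta Angle(s) in degrees.
#' @return Integer quadrant indices in `1..8`.
#' @export
quadrant_of <- function(theta) {
  as.integer(floor(((theta %% 360) + 22.5) / 45) %% 8 + 1)
}

#' Three-section, eight-quadrant stress summary
#'
#' Averages each stress component over every (section, 45-degree quadrant,
#' surface) cell, per phase: the tabular form of the polar stress plots.
#' Cells with no points are kept in the table with `NA` means and
#' `missing = TRUE` rather than silently dropped.
#'
#' @param sections A sectioned [stress_field()] from [extract_sections()].
#' @return A tibble of class `quadrant_summary` with columns `phase`,
#'   `section`, `quadrant`, `surface`, `mean_S_C`, `mean_S_L`, `n`,
#'   `missing`; 3 x 8 x 2 = 48 rows per phase, ordered section-major.
#' @export
quadrant_summary <- function(sections) {
  stopifnot("section" %in% names(sections), nrow(sections) > 0)
  filled <- sections |>
    dplyr::mutate(quadrant = quadrant_of(.data$theta)) |>
    dplyr::group_by(.data$phase, .data$section, .data$quadrant, .data$surface) |>
    dplyr::summarise(mean_S_C = mean(.data$S_C), mean_S_L = mean(.data$S_L),
                     n = dplyr::n(), .groups = "drop")
  grid <- tidyr::expand_grid(phase = unique(sections$phase),
                             section = c("A", "B", "C"),
                             quadrant = 1:8,
                             surface = c("inner", "outer"))
  out <- grid |>
    dplyr::left_join(filled, by = c("phase", "section", "quadrant", "surface")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  missing = .data$n == 0L) |>
    dplyr::arrange(.data$phase, .data$section, .data$quadrant, .data$surface)
  class(out) <- unique(c("quadrant_summary", class(out)))
  out
}

#' Transmural stress differences and sign-change flags
#'
#' Inner-minus-outer difference of each quadrant mean, and a flag for the
#' quadrants whose longitudinal (or circumferential) stress changes sign
#' through the wall from tensile inside to compressive outside - the arc
#' bending signature implicated in dissection initiation.
#'
#' @param summary A [quadrant_summary()] containing both surfaces.
#' @return A tibble with one row per (phase, section, quadrant):
#'   `delta_S_C`, `delta_S_L` (inner minus outer, kPa) and
#'   `sign_change_S_C`, `sign_change_S_L` (`TRUE` when inner > 0 and
#'   outer < 0).
#' @export
transmural_delta <- function(summary) {
  if (!all(c("inner", "outer") %in% summary$surface)) {
    stop("summary must contain both inner and outer surfaces", call. = FALSE)
  }
  wide <- summary |>
    dplyr::select("phase", "section", "quadrant", "surface",
                  "mean_S_C", "mean_S_L") |>
    tidyr::pivot_wider(names_from = "surface",
                       values_from = c("mean_S_C", "mean_S_L"))
  if (any(is.na(wide$mean_S_L_inner) != is.na(wide$mean_S_L_outer))) {
    stop("some quadrants have only one surface sampled", call. = FALSE)
  }
  wide |>
    dplyr::mutate(
      delta_S_C = .data$mean_S_C_inner - .data$mean_S_C_outer,
      delta_S_L = .data$mean_S_L_inner - .data$mean_S_L_outer,
      sign_change_S_C = .data$mean_S_C_inner > 0 & .data$mean_S_C_outer < 0,
      sign_change_S_L = .data$mean_S_L_inner > 0 & .data$mean_S_L_outer < 0
    ) |>
    dplyr::select("phase", "section", "quadrant", "delta_S_C", "delta_S_L",
                  "sign_change_S_C", "sign_change_S_L")
}

#' Write a quadrant summary CSV
#'
#' @param summary A [quadrant_summary()].
#' @param path CSV file path.
#' @export
write_quadrant_csv <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}
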