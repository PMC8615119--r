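# Minimal legacy-ASCII VTK polydata I/O for stress-field point clouds.
# Point coordinates plus the per-point arrays S_C, S_L, arclength, theta,
# surface (0 = inner, 1 = outer) and phase (1 = systole, 0 = diastole).
# Written with 17 significant digits so doubles round-trip exactly.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a stress field as a legacy-ASCII VTK polydata file
#'
#' @param field A [stress_field()] with point coordinates `x`, `y`, `z`.
#' @param path Output `.vtk` path.
#' @return The path, invisibly.
#' @export
write_stress_vtk <- function(field, path) {
  need <- c("x", "y", "z", "s", "theta", "surface", "S_C", "S_L", "phase")
  if (!all(need %in% names(field))) {
    stop("field must carry columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(field)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "aortic wall stress field",
               "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  writeLines(paste(fmt_num(field$x), fmt_num(field$y), fmt_num(field$z)), con)
  writeLines(sprintf("VERTICES %d %d", n, 2L * n), con)
  writeLines(paste(1L, seq_len(n) - 1L), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  scalar <- function(name, vals, type = "double") {
    writeLines(c(sprintf("SCALARS %s %s 1", name, type),
                 "LOOKUP_TABLE default"), con)
    writeLines(if (type == "int") format(as.integer(vals)) else fmt_num(vals),
               con)
  }
  scalar("S_C", field$S_C)
  scalar("S_L", field$S_L)
  scalar("arclength", field$s)
  scalar("theta", field$theta)
  scalar("surface", ifelse(field$surface == "outer", 1L, 0L), type = "int")
  scalar("phase", ifelse(field$phase == "systole", 1L, 0L), type = "int")
  invisible(path)
}

#' Read a stress field from a legacy-ASCII VTK polydata file
#'
#' Expects the layout produced by [write_stress_vtk()] (point-data arrays
#' `S_C`, `S_L`, `arclength`, `theta`, `surface`, `phase`).
#'
#' @param path Input `.vtk` path.
#' @return A [stress_field()] tibble with the coordinates restored.
#' @export
read_stress_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS ", lines)
  if (length(ip) != 1) stop("not a VTK points file: ", path, call. = FALSE)
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  coords <- scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE)
  xyz <- matrix(coords, ncol = 3, byrow = TRUE)
  arrays <- list()
  is_sc <- grep("^SCALARS ", lines)
  for (i in is_sc) {
    name <- strsplit(lines[i], "\\s+")[[1]][2]
    vals <- scan(text = lines[(i + 2):(i + 1 + n)], quiet = TRUE)
    arrays[[name]] <- vals
  }
  need <- c("S_C", "S_L", "arclength", "theta", "surface", "phase")
  if (!all(need %in% names(arrays))) {
    stop("VTK file lacks point-data arrays: ",
         paste(setdiff(need, names(arrays)), collapse = ", "), call. = FALSE)
  }
  stress_field(tibble::tibble(
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    s = arrays$arclength, theta = arrays$theta,
    surface = ifelse(arrays$surface == 1, "outer", "inner"),
    S_C = arrays$S_C, S_L = arrays$S_L,
    phase = ifelse(arrays$phase == 1, "systole", "diastole")
  ))
}
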