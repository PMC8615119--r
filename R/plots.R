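#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a biaxial fit
#'
#' Measured first-PK stresses against engineering strain in both material
#' directions, overlaid with the fitted constitutive response.
#'
#' @param object An `ho_fit` from [fit_ho()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ho_fit <- function(object, ...) {
  ds <- object$data
  long <- tibble::tibble(
    eng_strain = c(strain_invert(ds$E_circ), strain_invert(ds$E_long)),
    stress = c(ds$P_circ, ds$P_long),
    fitted = c(object$predictions$P_circ_fit, object$predictions$P_long_fit),
    direction = rep(c("circumferential", "longitudinal"), each = nrow(ds))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$eng_strain)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$stress,
                                     colour = .data$direction), alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted,
                                    colour = .data$direction)) +
    ggplot2::labs(x = "engineering strain", y = "first-PK stress (MPa)",
                  colour = NULL,
                  title = sprintf("Biaxial fit: r = %.3f, NRMSE = %.3f",
                                  object$r, object$nrmse)) +
    ggplot2::theme_minimal()
}

#' Plot a hemodynamic trace
#'
#' Left-ventricular and aortic pressure over time, with the LV volume on a
#' second panel.
#'
#' @param object A `hemo_trace` from [simulate_circulation()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hemo_trace <- function(object, ...) {
  tr <- object$trace
  long <- tidyr::pivot_longer(tr, c("p_lv", "p_ao", "v_lv"),
                              names_to = "signal")
  long$panel <- ifelse(long$signal == "v_lv", "volume (mL)",
                       "pressure (mmHg)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Pressure-volume loop of the final beat
#'
#' @param trace A `hemo_trace` from [simulate_circulation()].
#' @return A ggplot of the (volume, LV pressure) loop.
#' @export
plot_pv_loop <- function(trace) {
  beat <- trace$final_beat
  ggplot2::ggplot(beat, ggplot2::aes(x = .data$v_lv, y = .data$p_lv)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "LV volume (mL)", y = "LV pressure (mmHg)",
                  title = "Left-ventricular pressure-volume loop") +
    ggplot2::theme_minimal()
}

#' Polar plot of a quadrant summary
#'
#' Quadrant means of one stress component around the circumference, one
#' facet per section, coloured by surface - the tabular polar-plot view.
#'
#' @param object A [quadrant_summary()].
#' @param component `"S_L"` (default) or `"S_C"`.
#' @param ... Unused.
#' @return A ggplot in polar coordinates.
#' @export
autoplot.quadrant_summary <- function(object, component = c("S_L", "S_C"),
                                      ...) {
  component <- match.arg(component)
  col <- paste0("mean_", component)
  df <- object
  df$angle <- (df$quadrant - 1) * 45
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data[[col]],
                                   colour = .data$surface,
                                   group = .data$surface)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::coord_polar(start = -pi / 8) +
    ggplot2::scale_x_continuous(breaks = seq(0, 315, 45),
                                labels = c("anterior", "2", "minor curv.",
                                           "4", "posterior", "6",
                                           "major curv.", "8")) +
    ggplot2::facet_wrap(~section) +
    ggplot2::labs(x = NULL, y = paste(component, "(kPa)"), colour = NULL) +
    ggplot2::theme_minimal()
}
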