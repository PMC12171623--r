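# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cluster trajectory
#'
#' Normalized radius `R/R0` of every size class against time (in drive
#' cycles), with the analysis window shaded.
#'
#' @param object A [run_simulation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cav_trajectory <- function(object, ...) {
  scen <- attr(object, "scenario")
  drive <- attr(object, "drive")
  controls <- attr(object, "controls")
  R0 <- scen$population$radii
  q <- length(R0)
  long <- purrr::map_dfr(seq_len(q), function(i) {
    tibble::tibble(cycle = object$t * drive$frequency,
                   ratio = object[[paste0("R_", i)]] / R0[i],
                   class = sprintf("%g um", R0[i] * 1e6))
  })
  long$class <- factor(long$class, levels = sprintf("%g um", R0 * 1e6))
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$ratio,
                                     colour = .data$class)) +
    ggplot2::annotate("rect", xmin = controls$window[1],
                      xmax = controls$window[2], ymin = -Inf, ymax = Inf,
                      alpha = 0.08) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (drive cycles)", y = expression(R / R[0]),
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot a threshold curve
#'
#' Cavitation threshold against frequency; points above the search ceiling
#' are dropped. Facetted by medium when a `medium` column is present (as in
#' [composition_study()] output).
#'
#' @param object A [threshold_vs_frequency()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cav_threshold_curve <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !.data$above_ceiling)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$frequency / 1e3,
                                        .data$threshold / 1e3)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "frequency (kHz)", y = "cavitation threshold (kPa)") +
    ggplot2::theme_minimal()
  if ("medium" %in% names(df))
    p <- p + ggplot2::aes(colour = .data$medium)
  p
}

#' Plot a fitted power law over its data
#'
#' @param object A [fit_power_law()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cav_powerlaw <- function(object, ...) {
  fgrid <- exp(seq(log(object$frequency_range[1]),
                   log(object$frequency_range[2]), length.out = 200))
  line <- tibble::tibble(frequency = fgrid,
                         threshold = predict(object, fgrid))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$frequency / 1e3,
                                            .data$threshold / 1e3)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "red") +
    ggplot2::labs(x = "frequency (kHz)", y = "cavitation threshold (kPa)",
                  subtitle = sprintf("P = %.3g f^%.2f + %.3g (Pa, Hz)",
                                     object$A, object$alpha, object$B)) +
    ggplot2::theme_minimal()
}

#' Plot a parameter map
#'
#' Heat map of the threshold over the `(G, mu)` grid, or a line over the
#' bubble-number grid, depending on which study produced the map.
#'
#' @param object A [viscoelastic_map()] or [number_study()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cav_parameter_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if ("shear_modulus" %in% names(df)) {
    ggplot2::ggplot(df, ggplot2::aes(.data$shear_modulus / 1e3,
                                     .data$viscosity * 1e3,
                                     fill = .data$threshold / 1e3)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(name = "threshold (kPa)") +
      ggplot2::labs(x = "shear modulus (kPa)", y = "viscosity (mPa s)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$total_number,
                                     .data$threshold / 1e3)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "total bubble number",
                    y = "cavitation threshold (kPa)") +
      ggplot2::theme_minimal()
  }
}
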