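# ggplot2 visualisations for trajectories, fits, posteriors and scans.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated switch trajectory
#'
#' DNA-state concentrations (reduced model) or aggregated group totals
#' (mechanistic model) over time.
#'
#' @param object A `switch_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot switch_trajectory
#' @export
autoplot.switch_trajectory <- function(object, ...) {
  if (identical(attr(object, "model"), "reduced")) {
    long <- tidyr::pivot_longer(
      object[, c("time", "D_S1", "D_tS1", "D_tS2", "D_SX", "D_S2")],
      -"time", names_to = "state", values_to = "concentration")
  } else {
    on <- percent_car(object, "ON")
    long <- tibble::tibble(time = rep(on$time, 2),
                           state = rep(c("expressing %", "state-1 %"),
                                       each = nrow(on)),
                           concentration = c(on$percent, 100 - on$percent))
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$concentration,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "concentration (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the four time-course datasets, optionally with a fitted simulation
#'
#' @param data Tidy time-course tibble.
#' @param fit Optional `switch_fit`; its best-fit simulation is overlaid.
#' @return A ggplot object, faceted by dose.
#' @export
plot_timecourses <- function(data, fit = NULL) {
  g <- ggplot2::ggplot(data, ggplot2::aes(x = .data$day,
                                          y = .data$percent_car,
                                          colour = .data$switch)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~dose_uM, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "day", y = "percent CAR expression", colour = NULL) +
    ggplot2::ylim(0, NA) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    sim <- fit$residuals
    g <- g + ggplot2::geom_line(
      data = sim, ggplot2::aes(y = .data$percent_car_sim))
  }
  g
}

#' Plot marginal posteriors of an ABC-SMC run
#'
#' @param object An `abc_smc_result`.
#' @param population Population index (default last).
#' @param ... Unused.
#' @return A ggplot object with one density panel per parameter.
#' @method autoplot abc_smc_result
#' @export
autoplot.abc_smc_result <- function(object,
                                    population = length(object$populations),
                                    ...) {
  h <- posterior_summary(object$populations[[population]])$histograms
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_col(width = NULL) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "parameter value", y = "weighted density") +
    ggplot2::theme_minimal()
}

#' Plot a dose-response curve of switching response time
#'
#' @param curve A [dose_response()] result.
#' @return A ggplot object (log dose axis).
#' @export
plot_dose_response <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$dose_uM,
                                      y = .data$response_time,
                                      colour = .data$switch)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "4-OHT dose (uM)", y = "response time (days)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of the FlpO-fold by dose trade-off grid
#'
#' @param grid A [tradeoff_grid()] result.
#' @return A ggplot object faceted by switch.
#' @export
plot_tradeoff <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$dose_uM, y = .data$fold,
                                     fill = .data$response_time)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~switch) +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = "4-OHT dose (uM)", y = "FlpO expression fold",
                  fill = "response\ntime (d)") +
    ggplot2::theme_minimal()
}
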