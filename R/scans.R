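# Post-fit analyses: one-at-a-time parameter sensitivity of response time,
# dose-response curves, FlpO-expression fold-change scans, and the
# dose-by-expression trade-off grid.

#' @keywords internal
#' ON and OFF response times for one parameter set at one dose.
#' One dense simulation serves both observables. A solver failure yields
#' censored entries at the horizon.
response_times_at <- function(params, dose_uM = 1,
                              dose_map = dose_condition(1), horizon = 10,
                              dt = 0.005, solver = solver_config()) {
  dc <- dose_condition(dose_uM, dose_map$alpha_d_at_1uM, dose_map$oht0_at_1uM)
  grid <- seq(0, horizon, by = dt)
  traj <- tryCatch(
    simulate_switch(params, dose = dc, t_grid = grid, solver = solver),
    error = function(e) NULL)
  if (is.null(traj)) {
    cens <- structure(list(value = horizon, censored = TRUE,
                           horizon = horizon), class = "response_time_result")
    return(list(ON = cens, OFF = cens, failed = TRUE))
  }
  list(ON = response_time(percent_car(traj, "ON"), "ON", horizon),
       OFF = response_time(percent_car(traj, "OFF"), "OFF", horizon),
       failed = FALSE)
}

#' @keywords internal
scale_fitted <- function(params, name, factor) {
  params[[name]] <- params[[name]] * factor
  params
}

#' One-at-a-time sensitivity scan of switching response time
#'
#' Perturbs each fitted rate constant multiplicatively over a factor grid
#' spanning up to two orders of magnitude either side of its baseline value
#' and recomputes the ON and OFF response times at the induced dose. Grid
#' points whose simulation fails are recorded as censored and flagged.
#'
#' @param params Baseline [reduced_parameters()] or
#'   [mechanistic_parameters()].
#' @param factor_grid Multiplicative factors; default 19 log-spaced points
#'   over `[1e-2, 1e2]` (nine per side plus the identity).
#' @param dose_uM Induction dose for the scan (default 1 uM).
#' @param dose_map,horizon,solver Simulation settings.
#' @return A tibble of class `sensitivity_table`: `parameter`, `factor`,
#'   `switch`, `response_time`, `censored`, `failed`.
#' @export
sensitivity_scan <- function(params, factor_grid = 10^seq(-2, 2,
                                                          length.out = 19),
                             dose_uM = 1, dose_map = dose_condition(1),
                             horizon = 10, solver = solver_config()) {
  fitted <- if (inherits(params, "reduced_parameters")) reduced_fitted_names()
            else mechanistic_fitted_names()
  base <- response_times_at(params, dose_uM, dose_map, horizon,
                            solver = solver)
  if (base$failed) stop("baseline parameterization failed to simulate")
  rows <- list()
  for (nm in fitted) {
    for (f in factor_grid) {
      rt <- if (f == 1) base
            else response_times_at(scale_fitted(params, nm, f), dose_uM,
                                   dose_map, horizon, solver = solver)
      for (sw in c("ON", "OFF")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          parameter = nm, factor = f, switch = sw,
          response_time = rt[[sw]]$value, censored = rt[[sw]]$censored,
          failed = rt$failed)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "baseline") <- c(ON = base$ON$value, OFF = base$OFF$value)
  class(out) <- c("sensitivity_table", class(out))
  out
}

#' Rank parameters by response-time sensitivity
#'
#' Sensitivity of a parameter is the largest absolute log-change in response
#' time (over both switches and all factors) relative to the baseline.
#'
#' @param table A [sensitivity_scan()] result.
#' @return Tibble `parameter`, `sensitivity`, `rank` (1 = most sensitive).
#' @export
sensitivity_ranking <- function(table) {
  base <- attr(table, "baseline")
  tab <- dplyr::mutate(table,
                       base_rt = base[.data$switch],
                       logchange = abs(log(pmax(.data$response_time, 1e-6) /
                                           pmax(.data$base_rt, 1e-6))))
  out <- dplyr::summarise(dplyr::group_by(tab, .data$parameter),
                          sensitivity = max(.data$logchange),
                          .groups = "drop")
  out <- dplyr::arrange(out, dplyr::desc(.data$sensitivity))
  out$rank <- seq_len(nrow(out))
  out
}

#' Dose-response curve of switching response time
#'
#' Response time per 4-OHT dose for both switches; each dose is an
#' independent simulation (no state carries over between grid points).
#'
#' @param params Parameter set.
#' @param dose_grid Doses in uM; default 21 log-spaced points over
#'   `[1e-1, 1e1]`.
#' @param dose_map,horizon,solver Simulation settings.
#' @return A tibble of class `dose_response_curve`: `dose_uM`, `switch`,
#'   `response_time`, `censored`.
#' @export
dose_response <- function(params, dose_grid = 10^seq(-1, 1, length.out = 21),
                          dose_map = dose_condition(1), horizon = 10,
                          solver = solver_config()) {
  if (any(dose_grid < 0)) stop("doses must be >= 0")
  rows <- list()
  for (d in dose_grid) {
    rt <- response_times_at(params, d, dose_map, horizon, solver = solver)
    for (sw in c("ON", "OFF")) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        dose_uM = d, switch = sw, response_time = rt[[sw]]$value,
        censored = rt[[sw]]$censored)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dose_response_curve", class(out))
  out
}

#' FlpO-expression fold-change scan
#'
#' Jointly multiplies the two FlpO expression rates (`alpha_a`, `alpha_b`)
#' by each fold and returns full ON and OFF percent-CAR time courses under
#' induced and uninduced conditions, exposing both the faster response and
#' the increased basal switching that higher expression brings.
#'
#' @param params Parameter set.
#' @param folds Fold changes (default 1, 2, 5).
#' @param doses Doses in uM (default 0 and 1).
#' @param dose_map,horizon,solver Simulation settings.
#' @param dt Output grid spacing in days.
#' @return Tibble `fold`, `dose_uM`, `switch`, `time`, `percent`.
#' @export
fold_change_scan <- function(params, folds = c(1, 2, 5), doses = c(0, 1),
                             dose_map = dose_condition(1), horizon = 10,
                             solver = solver_config(), dt = 0.01) {
  if (any(folds <= 0)) stop("folds must be > 0")
  grid <- seq(0, horizon, by = dt)
  rows <- list()
  for (f in folds) {
    pf <- scale_fitted(scale_fitted(params, "alpha_a", f), "alpha_b", f)
    for (d in doses) {
      dc <- dose_condition(d, dose_map$alpha_d_at_1uM, dose_map$oht0_at_1uM)
      traj <- simulate_switch(pf, dose = dc, t_grid = grid, solver = solver)
      for (sw in c("ON", "OFF")) {
        pc <- percent_car(traj, sw)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          fold = f, dose_uM = d, switch = sw, time = pc$time,
          percent = pc$percent)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Trade-off grid: FlpO expression fold versus 4-OHT dose
#'
#' Response-time matrix over a joint grid of FlpO-expression fold changes
#' (applied to `alpha_a` and `alpha_b` together) and 4-OHT doses, for both
#' switches. Cells that never reach the 90% level within the horizon are
#' censored at the horizon value.
#'
#' @param params Parameter set.
#' @param fold_grid Fold changes; default 9 log-spaced points over one order
#'   of magnitude either side of baseline.
#' @param dose_grid Doses in uM; default 9 log-spaced points over
#'   `[1e-1, 1e1]`.
#' @param dose_map,horizon,solver Simulation settings.
#' @return A tibble of class `tradeoff_grid`: `fold`, `dose_uM`, `switch`,
#'   `response_time`, `censored`.
#' @export
tradeoff_grid <- function(params, fold_grid = 10^seq(-1, 1, length.out = 9),
                          dose_grid = 10^seq(-1, 1, length.out = 9),
                          dose_map = dose_condition(1), horizon = 10,
                          solver = solver_config()) {
  if (!length(fold_grid) || !length(dose_grid)) stop("grids must be non-empty")
  rows <- list()
  for (f in fold_grid) {
    pf <- scale_fitted(scale_fitted(params, "alpha_a", f), "alpha_b", f)
    for (d in dose_grid) {
      rt <- response_times_at(pf, d, dose_map, horizon, solver = solver)
      for (sw in c("ON", "OFF")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          fold = f, dose_uM = d, switch = sw,
          response_time = rt[[sw]]$value, censored = rt[[sw]]$censored)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tradeoff_grid", class(out))
  out
}
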