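# Time-course simulation of either model, dose mapping, and the observables:
# percent CAR expression and the 90%-of-change response time.

#' Dose condition for 4-OHT induction
#'
#' Maps a 4-OHT concentration in uM to the model inputs. The drug enters the
#' model as a source rate `alpha_d` (continuous media replenishment) and,
#' optionally, as an initial concentration; both channels scale linearly with
#' dose. The default calibration drives induction purely through `alpha_d`.
#'
#' @param dose_uM 4-OHT dose in uM (non-negative).
#' @param alpha_d_at_1uM Source rate (a.u./day) corresponding to 1 uM.
#' @param oht0_at_1uM Initial 4-OHT concentration (a.u.) corresponding to
#'   1 uM; default 0.
#' @return An object of class `dose_condition` with fields `dose_uM`,
#'   `alpha_d`, `oht0`.
#' @export
dose_condition <- function(dose_uM, alpha_d_at_1uM = 1, oht0_at_1uM = 0) {
  if (!is.finite(dose_uM) || dose_uM < 0) stop("dose_uM must be >= 0")
  structure(list(dose_uM = dose_uM,
                 alpha_d = alpha_d_at_1uM * dose_uM,
                 oht0 = oht0_at_1uM * dose_uM,
                 alpha_d_at_1uM = alpha_d_at_1uM,
                 oht0_at_1uM = oht0_at_1uM),
            class = "dose_condition")
}

#' Solver settings
#'
#' @param rtol,atol Relative/absolute integration tolerances.
#' @param method deSolve integration method (default `"lsoda"`,
#'   stiff-capable).
#' @param max_step Maximum internal step size (days).
#' @return A `solver_config` list.
#' @export
solver_config <- function(rtol = 1e-8, atol = 1e-10, method = "lsoda",
                          max_step = Inf) {
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive")
  structure(list(rtol = rtol, atol = atol, method = method,
                 max_step = max_step), class = "solver_config")
}

#' Simulate the switch model over time
#'
#' Integrates the reduced or mechanistic model from the standard initial
#' condition (all DNA in State 1, FlpO pools empty, 4-OHT at the dose-mapped
#' level) over a time grid.
#'
#' @param params A [reduced_parameters()] or [mechanistic_parameters()]
#'   object, or a prebuilt `recombination_network`. For a `dose` with a
#'   nonzero `alpha_d`, the parameter set's own `alpha_d` is overridden by
#'   the dose mapping.
#' @param dose A [dose_condition()]; default 0 uM.
#' @param t_grid Time grid in days (strictly increasing, starting at 0).
#' @param solver A [solver_config()].
#' @param total_dna Total genomic DNA at time zero (a.u.).
#' @return A tibble of class `switch_trajectory` with a `time` column and one
#'   column per state variable; attribute `model` is `"reduced"` or
#'   `"mechanistic"`.
#' @export
simulate_switch <- function(params, dose = dose_condition(0),
                            t_grid = seq(0, 10, by = 0.01),
                            solver = solver_config(), total_dna = 1) {
  stopifnot(inherits(dose, "dose_condition"))
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing")
  }
  if (inherits(params, "reduced_parameters")) {
    p <- params
    p$alpha_d <- dose$alpha_d
    y0 <- reduced_initial_state(dose$oht0, total_dna)
    out <- deSolve::ode(y = y0, times = t_grid, func = "derivs_reduced",
                        parms = reduced_param_vector(p),
                        dllname = "flpswitch", initfunc = "init_reduced",
                        method = solver$method, rtol = solver$rtol,
                        atol = solver$atol, hmax = solver$max_step)
    model <- "reduced"
  } else {
    net <- if (inherits(params, "recombination_network")) params
           else build_mechanistic_network(params)
    net$rate_values[["alpha_d"]] <- dose$alpha_d
    rates <- as.numeric(net$rate_values[net$reactions$rate_ref])
    i1 <- net$ridx1 + 1L; i2 <- net$ridx2 + 1L
    S <- net$stoich
    rhs <- function(t, y, parms) {
      cc <- c(1, y)
      list(as.numeric(S %*% (rates * cc[i1] * cc[i2])))
    }
    y0 <- mechanistic_initial_state(net, oht0 = dose$oht0,
                                    total_dna = total_dna)
    out <- deSolve::ode(y = y0, times = t_grid, func = rhs, parms = NULL,
                        method = solver$method, rtol = solver$rtol,
                        atol = solver$atol, hmax = solver$max_step)
    model <- "mechanistic"
  }
  diag <- attr(out, "istate")
  if (!is.null(diag) && diag[1] < 0) {
    stop("integration failed (istate = ", diag[1], ")")
  }
  if (nrow(out) < length(t_grid) || any(!is.finite(out))) {
    stop("integration failed: non-finite or truncated solver output")
  }
  traj <- tibble::as_tibble(as.data.frame(out))
  names(traj)[1] <- "time"
  attr(traj, "model") <- model
  if (model == "mechanistic") attr(traj, "network") <- net
  class(traj) <- c("switch_trajectory", class(traj))
  traj
}

#' Percent CAR expression along a trajectory
#'
#' For the ON switch the expressing genetic states are the two transient
#' states and State 2; for the OFF switch (blank sequence and CAR gene
#' swapped) only State 1 expresses. The mechanistic model is aggregated with
#' [state_totals()] group weights before the percentage is formed.
#'
#' @param traj A `switch_trajectory`.
#' @param orientation `"ON"` or `"OFF"`.
#' @return Tibble with columns `time` and `percent`.
#' @export
percent_car <- function(traj, orientation = c("ON", "OFF")) {
  orientation <- match.arg(orientation)
  if (identical(attr(traj, "model"), "mechanistic")) {
    net <- attr(traj, "network")
    sp <- net$species
    w <- sp$weight
    in_s1 <- sp$group %in% "state1"
    in_ex <- sp$group %in% "expressing"
    M <- as.matrix(traj[, sp$name])
    s1 <- as.numeric(M[, in_s1, drop = FALSE] %*% w[in_s1])
    ex <- as.numeric(M[, in_ex, drop = FALSE] %*% w[in_ex])
  } else {
    s1 <- traj$D_S1
    ex <- traj$D_tS1 + traj$D_tS2 + traj$D_S2
  }
  tot <- s1 + ex
  if (any(tot <= 0)) stop("zero genomic total along trajectory")
  pct <- if (orientation == "ON") 100 * ex / tot else 100 * s1 / tot
  tibble::tibble(time = traj$time, percent = pct)
}

#' 90%-of-change response time
#'
#' For the ON switch, the earliest time at which the series reaches 90% of
#' its maximum over the horizon; for the OFF switch, the earliest time at
#' which the drop from the initial value reaches 90% of the total decrease.
#' Crossings are located by linear interpolation between samples; a series
#' that never reaches the level is censored at the horizon. Degenerate
#' cases: a constant positive ON series is already at 90% of its maximum
#' (response time 0), but an ON series that never expresses at all
#' (maximum 0) and an OFF series that never decreases are censored — the
#' switch never acts.
#'
#' @param series Data frame with a time column and a value column (the first
#'   two columns are used; [percent_car()] output works directly).
#' @param orientation `"ON"` or `"OFF"`.
#' @param horizon Analysis horizon in days (default 10).
#' @return A list of class `response_time_result` with `value` (days),
#'   `censored`, and `horizon`.
#' @export
response_time <- function(series, orientation = c("ON", "OFF"), horizon = 10) {
  orientation <- match.arg(orientation)
  if (is.null(dim(series)) || nrow(series) == 0) stop("empty series")
  t <- series[[1]]; v <- series[[2]]
  keep <- t <= horizon + 1e-12
  t <- t[keep]; v <- v[keep]
  if (length(t) == 0) stop("series has no samples within the horizon")
  never_acts <- FALSE
  if (orientation == "ON") {
    level <- 0.9 * max(v)
    reached <- v >= level
    never_acts <- max(v) <= 1e-9
  } else {
    drop_total <- v[1] - min(v)
    level <- v[1] - 0.9 * drop_total
    reached <- (v[1] - v) >= 0.9 * drop_total - 1e-12
    never_acts <- drop_total <= 1e-9
  }
  if (never_acts || !any(reached)) {
    return(structure(list(value = horizon, censored = TRUE,
                          horizon = horizon), class = "response_time_result"))
  }
  i <- which(reached)[1]
  if (i == 1) {
    val <- t[1]
  } else {
    # linear interpolation of the crossing between samples i-1 and i
    v0 <- v[i - 1]; v1 <- v[i]
    if (orientation == "OFF") { v0 <- -v0; v1 <- -v1; level <- -level }
    frac <- if (abs(v1 - v0) < 1e-300) 0 else (level - v0) / (v1 - v0)
    frac <- min(max(frac, 0), 1)
    val <- t[i - 1] + frac * (t[i] - t[i - 1])
  }
  structure(list(value = val, censored = FALSE, horizon = horizon),
            class = "response_time_result")
}

#' @export
print.response_time_result <- function(x, ...) {
  cat(sprintf("<response_time> %.3f days%s (horizon %g d)\n", x$value,
              if (x$censored) " [censored]" else "", x$horizon))
  invisible(x)
}

#' Normalize time-course datasets to the global maximum
#'
#' Rescales percent-CAR values so that the single largest value across all
#' series maps to 100, the convention used to restrict attention to the
#' functionally viable (recombinase- and switch-positive) cell population.
#'
#' @param datasets Tidy tibble with a `percent_car` column (any other
#'   columns are preserved).
#' @return The rescaled tibble.
#' @export
normalize_to_global_max <- function(datasets) {
  gm <- max(datasets$percent_car)
  if (!is.finite(gm) || gm <= 0) stop("all-zero or non-finite datasets")
  dplyr::mutate(datasets, percent_car = .data$percent_car * 100 / gm)
}

# ---- fast inference path ----------------------------------------------------

#' @keywords internal
#' Simulate both observables at a set of doses and observation days.
#' Returns a tibble (switch, dose_uM, day, percent_car); one ODE solve per
#' dose serves the ON and OFF observables.
simulate_percent_grid <- function(params, doses = c(0, 1), days = 1:10,
                                  dose_map = dose_condition(1),
                                  solver = solver_config()) {
  out <- vector("list", length(doses))
  for (k in seq_along(doses)) {
    dc <- dose_condition(doses[k], dose_map$alpha_d_at_1uM,
                         dose_map$oht0_at_1uM)
    traj <- simulate_switch(params, dose = dc,
                            t_grid = c(0, days), solver = solver)
    keep <- traj$time %in% days
    on <- percent_car(traj, "ON")$percent[keep]
    off <- percent_car(traj, "OFF")$percent[keep]
    out[[k]] <- tibble::tibble(
      switch = rep(c("ON", "OFF"), each = length(days)),
      dose_uM = doses[k], day = rep(days, 2),
      percent_car = c(on, off))
  }
  dplyr::bind_rows(out)
}
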