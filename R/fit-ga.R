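# Global parameter estimation against the four time-course datasets with a
# bounded genetic algorithm.

#' Absolute-error distance between simulated and observed time courses
#'
#' The fitting distance is one tenth of the sum of absolute residuals across
#' all forty paired values of the four datasets (as defined, the divisor is
#' the ten observation days, not the forty points).
#'
#' @param simulated,observed Numeric vectors of paired values, or tidy data
#'   frames with columns `switch`, `dose_uM`, `day`, `percent_car` which are
#'   joined on the identifying columns before comparison.
#' @return A non-negative scalar distance.
#' @export
error_distance <- function(simulated, observed) {
  if (is.data.frame(simulated) && is.data.frame(observed)) {
    key <- c("switch", "dose_uM", "day")
    m <- dplyr::inner_join(simulated, observed, by = key,
                           suffix = c("_sim", "_obs"))
    if (nrow(m) != nrow(simulated) || nrow(m) != nrow(observed)) {
      stop("simulated and observed datasets do not pair one-to-one")
    }
    return(sum(abs(m$percent_car_sim - m$percent_car_obs)) / 10)
  }
  if (length(simulated) != length(observed)) {
    stop("length mismatch: ", length(simulated), " vs ", length(observed))
  }
  sum(abs(simulated - observed)) / 10
}

#' Genetic-algorithm configuration
#'
#' Defaults are the desk-scale setting (population 200 over 150
#' generations); the study-scale setting runs a population of at least 1000
#' over 1000 generations. Operators: tournament selection, uniform
#' crossover, per-gene Gaussian mutation with a geometrically annealed step
#' size, clipped to the search bounds, with elitism.
#'
#' @param population_size Number of candidates per generation (>= 2).
#' @param generations Number of generations.
#' @param seed Integer seed; the run is fully reproducible given the seed.
#' @param lower,upper Per-parameter search bounds (recycled); default the
#'   unit interval imposed on all fitted rate constants.
#' @param crossover_prob Probability a child is formed by uniform crossover.
#' @param mutation_prob Per-gene mutation probability.
#' @param mutation_sd_start,mutation_sd_end Gaussian mutation step size at
#'   the first and last generation (geometric interpolation between them).
#' @param tournament_size Tournament size for parent selection.
#' @param n_elite Number of best candidates copied unchanged.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 200, generations = 150, seed = 1L,
                      lower = 0, upper = 1, crossover_prob = 0.9,
                      mutation_prob = 0.15, mutation_sd_start = 0.15,
                      mutation_sd_end = 0.01, tournament_size = 3,
                      n_elite = 2) {
  if (population_size < 2) stop("population_size must be >= 2")
  if (any(upper < lower)) stop("bounds must satisfy lower <= upper")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 seed = as.integer(seed), lower = lower, upper = upper,
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 mutation_sd_start = mutation_sd_start,
                 mutation_sd_end = mutation_sd_end,
                 tournament_size = as.integer(tournament_size),
                 n_elite = as.integer(n_elite)),
            class = "ga_config")
}

#' @keywords internal
#' Build the objective closure: theta (named fitted vector) -> distance to
#' the observed four datasets. One ODE solve per dose serves both switch
#' orientations.
make_objective <- function(data, model = c("reduced", "mechanistic"),
                           dose_map = dose_condition(1),
                           solver = solver_config()) {
  model <- match.arg(model)
  data <- dplyr::arrange(data, .data$switch, .data$dose_uM, .data$day)
  target <- data$percent_car
  doses <- sort(unique(data$dose_uM))
  days <- sort(unique(data$day))
  if (model == "mechanistic") {
    return(function(theta) {
      params <- as_mechanistic_parameters(theta)
      sim <- simulate_percent_grid(params, doses = doses, days = days,
                                   dose_map = dose_map, solver = solver)
      sim <- dplyr::arrange(sim, .data$switch, .data$dose_uM, .data$day)
      error_distance(sim$percent_car, target)
    })
  }
  # Lean path for the reduced model: one compiled-RHS solve per dose, the
  # prediction vector assembled in (switch, dose, day) order to pair with
  # the arranged data. The GA and ABC inner loops live here.
  par_order <- c("alpha_a", "alpha_b", "alpha_d", "beta_p", "beta_d",
                 "K_a", "K_b", "k1", "k2", "k3", "k4", "k_r", "delta",
                 "vbar")
  times <- c(0, days)
  keep <- seq_along(days) + 1L
  function(theta) {
    if (any(theta < 0)) stop("negative rate constant")
    on <- off <- matrix(NA_real_, length(days), length(doses))
    for (k in seq_along(doses)) {
      pv <- c(theta[c("alpha_a", "alpha_b")],
              alpha_d = dose_map$alpha_d_at_1uM * doses[k],
              theta[c("beta_p", "beta_d", "K_a", "K_b",
                      "k1", "k2", "k3", "k4", "k_r", "delta")],
              vbar = 0.3)
      y0 <- reduced_initial_state(dose_map$oht0_at_1uM * doses[k], 1)
      out <- deSolve::lsoda(y0, times, "derivs_reduced", pv[par_order],
                            dllname = "flpswitch",
                            initfunc = "init_reduced",
                            rtol = solver$rtol, atol = solver$atol,
                            hmax = solver$max_step)
      if (nrow(out) < length(times) || any(!is.finite(out))) {
        stop("integration failed")
      }
      s1 <- out[keep, "D_S1"]
      ex <- out[keep, "D_tS1"] + out[keep, "D_tS2"] + out[keep, "D_S2"]
      tot <- s1 + ex
      on[, k] <- 100 * ex / tot
      off[, k] <- 100 * s1 / tot
    }
    error_distance(c(as.numeric(off), as.numeric(on)), target)
  }
}

#' Fit the model to the four time-course datasets with a genetic algorithm
#'
#' Evolves a population of candidate parameter vectors inside the unit box,
#' scoring each candidate by simulating both dose conditions once and
#' evaluating the ON and OFF observables against all four datasets
#' simultaneously. Candidates whose simulation fails receive a penalty score
#' (ten times the worst finite score in the population) rather than crashing
#' the run. The best candidate ever seen is returned (elitism guarantees the
#' best-so-far error is non-increasing across generations).
#'
#' @param data Tidy tibble with columns `switch` (`"ON"`/`"OFF"`),
#'   `dose_uM`, `day`, `percent_car` covering both orientations at both
#'   doses.
#' @param model `"reduced"` (12 fitted parameters) or `"mechanistic"` (27).
#' @param config A [ga_config()].
#' @param dose_map A [dose_condition()] carrying the calibration constants.
#' @param solver A [solver_config()].
#' @param init_population Optional matrix (rows = candidates, named columns)
#'   of starting candidates injected into the initial population.
#' @param verbose Print best error once every 25 generations.
#' @return An object of class `switch_fit` with elements `parameters` (named
#'   best vector), `error`, `residuals` (per-point tibble), `evaluations`,
#'   `history` (best error per generation), `seed`, `model`, `config`.
#' @export
fit_ga <- function(data, model = c("reduced", "mechanistic"),
                   config = ga_config(), dose_map = dose_condition(1),
                   solver = solver_config(), init_population = NULL,
                   verbose = FALSE) {
  model <- match.arg(model)
  validate_timecourses(data)
  par_names <- if (model == "reduced") reduced_fitted_names()
               else mechanistic_fitted_names()
  p <- length(par_names)
  lower <- rep_len(config$lower, p); upper <- rep_len(config$upper, p)
  objective <- make_objective(data, model, dose_map, solver)
  score_one <- function(theta) {
    tryCatch(objective(stats::setNames(theta, par_names)),
             error = function(e) NA_real_)
  }

  set.seed(config$seed)
  n <- config$population_size
  pop <- matrix(stats::runif(n * p, lower, upper), nrow = n, byrow = TRUE)
  if (!is.null(init_population)) {
    init <- as.matrix(init_population)[, par_names, drop = FALSE]
    k <- min(nrow(init), n)
    pop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  colnames(pop) <- par_names

  evaluations <- 0L
  n_failed <- 0L
  eval_pop <- function(pop) {
    sc <- apply(pop, 1, score_one)
    evaluations <<- evaluations + nrow(pop)
    bad <- !is.finite(sc)
    n_failed <<- n_failed + sum(bad)
    if (any(bad)) {
      worst <- if (all(bad)) 1e6 else max(sc[!bad])
      sc[bad] <- 10 * max(worst, 1)
    }
    sc
  }
  scores <- eval_pop(pop)

  best_idx <- which.min(scores)
  best_theta <- pop[best_idx, ]
  best_error <- scores[best_idx]
  history <- numeric(config$generations)

  sd_sched <- config$mutation_sd_start *
    (config$mutation_sd_end / config$mutation_sd_start)^
    (seq_len(max(config$generations, 1)) / max(config$generations, 1))

  tournament <- function() {
    idx <- sample.int(n, config$tournament_size, replace = TRUE)
    idx[which.min(scores[idx])]
  }

  for (g in seq_len(config$generations)) {
    elite_idx <- order(scores)[seq_len(min(config$n_elite, n))]
    children <- matrix(NA_real_, nrow = n, ncol = p)
    children[seq_along(elite_idx), ] <- pop[elite_idx, , drop = FALSE]
    for (i in seq.int(length(elite_idx) + 1L, n)) {
      p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
      child <- if (stats::runif(1) < config$crossover_prob) {
        mask <- stats::runif(p) < 0.5
        ifelse(mask, p1, p2)
      } else p1
      mut <- stats::runif(p) < config$mutation_prob
      if (any(mut)) {
        child[mut] <- child[mut] + stats::rnorm(sum(mut), sd = sd_sched[g])
      }
      children[i, ] <- pmin(pmax(child, lower), upper)
    }
    colnames(children) <- par_names
    pop <- children
    scores <- eval_pop(pop)
    gi <- which.min(scores)
    if (scores[gi] < best_error) {
      best_error <- scores[gi]
      best_theta <- pop[gi, ]
    }
    history[g] <- best_error
    if (verbose && g %% 25 == 0) {
      message(sprintf("generation %d: best error %.4f", g, best_error))
    }
  }

  best_params <- stats::setNames(as.numeric(best_theta), par_names)
  as_params <- if (model == "reduced") as_reduced_parameters
               else as_mechanistic_parameters
  sim <- simulate_percent_grid(as_params(best_params),
                               doses = sort(unique(data$dose_uM)),
                               days = sort(unique(data$day)),
                               dose_map = dose_map, solver = solver)
  resid <- dplyr::inner_join(
    dplyr::arrange(data, .data$switch, .data$dose_uM, .data$day),
    dplyr::arrange(sim, .data$switch, .data$dose_uM, .data$day),
    by = c("switch", "dose_uM", "day"), suffix = c("_obs", "_sim"))
  resid$residual <- resid$percent_car_sim - resid$percent_car_obs

  structure(list(parameters = best_params, error = best_error,
                 residuals = tibble::as_tibble(resid),
                 evaluations = evaluations, failed_evaluations = n_failed,
                 history = history, seed = config$seed, model = model,
                 config = config, dose_map = dose_map),
            class = "switch_fit")
}

#' @export
print.switch_fit <- function(x, ...) {
  cat("<switch_fit>", x$model, "model; error =", format(x$error, digits = 5),
      "after", x$evaluations, "evaluations (seed", paste0(x$seed, ")"), "\n")
  print(round(x$parameters, 4))
  invisible(x)
}
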