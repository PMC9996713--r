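# Approximate Bayesian computation with sequential Monte Carlo: population
# rejection under a decreasing epsilon schedule, with importance weights and
# per-population acceptance logs.

#' ABC-SMC configuration
#'
#' The default epsilon schedule is the study-scale sequence; desk-scale runs
#' on synthetic data use a short reachable schedule such as `c(50, 20, 10)`.
#' The perturbation kernel is component-wise Gaussian with a scale equal to
#' half the weighted standard deviation of the previous population per
#' parameter (a uniform kernel of the same half-width is also available);
#' proposals outside the prior box are rejected before simulation.
#'
#' @param n_particles Particles per population (default 100).
#' @param epsilon_schedule Strictly decreasing thresholds.
#' @param lower,upper Uniform prior bounds per parameter (recycled).
#' @param kernel `"gaussian"` or `"uniform"`.
#' @param kernel_scale_factor Kernel scale as a fraction of the weighted
#'   standard deviation of the previous population (default 0.5).
#' @param max_draws Maximum proposals per population before the run stops
#'   and reports the last completed population (default 200000).
#' @param seed Integer seed.
#' @return An `abc_config` list.
#' @export
abc_config <- function(n_particles = 100,
                       epsilon_schedule = c(500, 250, 100, 50, 45, 40, 35,
                                            30, 29, 28.15),
                       lower = 0, upper = 1,
                       kernel = c("gaussian", "uniform"),
                       kernel_scale_factor = 0.5,
                       max_draws = 200000, seed = 1L) {
  kernel <- match.arg(kernel)
  if (n_particles < 1) stop("n_particles must be >= 1")
  if (any(diff(epsilon_schedule) >= 0)) {
    stop("epsilon_schedule must be strictly decreasing")
  }
  structure(list(n_particles = as.integer(n_particles),
                 epsilon_schedule = epsilon_schedule,
                 lower = lower, upper = upper, kernel = kernel,
                 kernel_scale_factor = kernel_scale_factor,
                 max_draws = as.integer(max_draws), seed = as.integer(seed)),
            class = "abc_config")
}

#' Fit the model by ABC with sequential Monte Carlo
#'
#' Population 1 is drawn from the uniform prior with rejection at the first
#' threshold; each later population is built by weighted resampling of the
#' previous one, kernel perturbation, prior-support rejection, simulation,
#' and acceptance at the current threshold, with importance weights updated
#' by the standard SMC rule (prior density over the kernel-weighted mixture).
#' The run stops early, reporting the last completed population, when a
#' population cannot be filled within `max_draws` proposals — the behaviour
#' observed at unreachable final thresholds.
#'
#' @param data Tidy tibble of the four time-course datasets (columns
#'   `switch`, `dose_uM`, `day`, `percent_car`).
#' @param model `"reduced"` or `"mechanistic"`.
#' @param config An [abc_config()].
#' @param dose_map A [dose_condition()] with the calibration constants.
#' @param solver A [solver_config()].
#' @param verbose Message per completed population.
#' @return An object of class `abc_smc_result`: list with `populations` (one
#'   `abc_population` per completed threshold: particles tibble, weights,
#'   errors, epsilon, particles_assessed, acceptance_percent), a Table-style
#'   `log` tibble, `reached_epsilon`, and `terminated_early`.
#' @export
abc_smc <- function(data, model = c("reduced", "mechanistic"),
                    config = abc_config(), dose_map = dose_condition(1),
                    solver = solver_config(), verbose = FALSE) {
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
  n <- config$n_particles
  populations <- list()
  terminated_early <- FALSE

  prev_particles <- NULL; prev_weights <- NULL
  for (t in seq_along(config$epsilon_schedule)) {
    eps <- config$epsilon_schedule[t]
    acc <- matrix(NA_real_, nrow = n, ncol = p, dimnames = list(NULL, par_names))
    errs <- numeric(n)
    prior_d <- numeric(n)
    assessed <- 0L
    filled <- 0L
    if (!is.null(prev_particles)) {
      sds <- apply(prev_particles, 2, function(x) {
        mu <- sum(prev_weights * x)
        sqrt(max(sum(prev_weights * (x - mu)^2), 0))
      })
      scale <- pmax(config$kernel_scale_factor * sds, 1e-4)
    }
    while (filled < n) {
      if (assessed >= config$max_draws) {
        terminated_early <- TRUE
        break
      }
      if (is.null(prev_particles)) {
        theta <- stats::runif(p, lower, upper)
      } else {
        j <- sample.int(n, 1, prob = prev_weights)
        theta <- prev_particles[j, ] + if (config$kernel == "gaussian") {
          stats::rnorm(p, sd = scale)
        } else {
          stats::runif(p, -scale, scale)
        }
        if (any(theta < lower | theta > upper)) {
          # outside prior support: rejected before simulation, not assessed
          next
        }
      }
      assessed <- assessed + 1L
      err <- score_one(theta)
      if (is.finite(err) && err < eps) {
        filled <- filled + 1L
        acc[filled, ] <- theta
        errs[filled] <- err
      }
    }
    if (filled < n) break

    if (is.null(prev_particles)) {
      w <- rep(1 / n, n)
    } else {
      w <- numeric(n)
      for (i in seq_len(n)) {
        if (config$kernel == "gaussian") {
          kd <- vapply(seq_len(n), function(j) {
            prod(stats::dnorm(acc[i, ], prev_particles[j, ], scale))
          }, numeric(1))
        } else {
          kd <- vapply(seq_len(n), function(j) {
            prod(ifelse(abs(acc[i, ] - prev_particles[j, ]) <= scale,
                        1 / (2 * scale), 0))
          }, numeric(1))
        }
        denom <- sum(prev_weights * kd)
        w[i] <- if (denom > 0) 1 / denom else 0
      }
      if (sum(w) <= 0) w <- rep(1, n)
      w <- w / sum(w)
    }

    populations[[length(populations) + 1L]] <- structure(list(
      particles = tibble::as_tibble(as.data.frame(acc)),
      weights = w, errors = errs, epsilon = eps,
      particles_assessed = assessed,
      acceptance_percent = 100 * n / assessed),
      class = "abc_population")
    if (verbose) {
      message(sprintf("epsilon %.4g: %d assessed, %.2f%% accepted",
                      eps, assessed, 100 * n / assessed))
    }
    prev_particles <- acc
    prev_weights <- w
    if (terminated_early) break
  }

  log <- tibble::tibble(
    epsilon = vapply(populations, `[[`, numeric(1), "epsilon"),
    particles_assessed = vapply(populations, `[[`, numeric(1),
                                "particles_assessed"),
    particles_accepted_percent = vapply(populations, `[[`, numeric(1),
                                        "acceptance_percent"))
  structure(list(populations = populations, log = log,
                 reached_epsilon = if (length(populations))
                   populations[[length(populations)]]$epsilon else NA_real_,
                 terminated_early = terminated_early ||
                   length(populations) < length(config$epsilon_schedule),
                 model = model, config = config, seed = config$seed),
            class = "abc_smc_result")
}

#' @export
print.abc_smc_result <- function(x, ...) {
  cat("<abc_smc_result>", length(x$populations), "populations;",
      "reached epsilon =", format(x$reached_epsilon), "\n")
  print(x$log)
  invisible(x)
}

#' @keywords internal
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (length(x) == 1) return(rep(x, length(probs)))
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Weighted posterior summary of an ABC population
#'
#' @param population An `abc_population` (one element of an
#'   `abc_smc_result`'s `populations`).
#' @param probs Quantile levels (default 5/25/50/75/95 percent).
#' @param bins Number of histogram bins per parameter marginal.
#' @return A list with `quantiles` (tibble: parameter, one column per
#'   quantile, weighted mean and sd) and `histograms` (tibble: parameter,
#'   bin midpoint, weighted density).
#' @export
posterior_summary <- function(population,
                              probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                              bins = 20) {
  if (!inherits(population, "abc_population") ||
      nrow(population$particles) == 0) {
    stop("non-empty abc_population required")
  }
  P <- population$particles
  w <- population$weights / sum(population$weights)
  qtab <- purrr::map_dfr(names(P), function(nm) {
    x <- P[[nm]]
    q <- weighted_quantile(x, w, probs)
    mu <- sum(w * x)
    tibble::tibble(parameter = nm,
                   !!!stats::setNames(as.list(q), paste0("q", probs * 100)),
                   mean = mu, sd = sqrt(max(sum(w * (x - mu)^2), 0)))
  })
  htab <- purrr::map_dfr(names(P), function(nm) {
    x <- P[[nm]]
    br <- seq(min(x), max(x), length.out = bins + 1)
    if (diff(range(x)) == 0) br <- c(x[1] - 0.5, x[1] + 0.5)
    cut_idx <- findInterval(x, br, rightmost.closed = TRUE,
                            all.inside = TRUE)
    dens <- vapply(seq_len(length(br) - 1), function(b) {
      sum(w[cut_idx == b]) / diff(br)[b]
    }, numeric(1))
    tibble::tibble(parameter = nm,
                   mid = (br[-1] + br[-length(br)]) / 2,
                   density = dens)
  })
  list(quantiles = qtab, histograms = htab)
}
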