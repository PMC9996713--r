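# Synthetic four-dataset time-course generator with known ground truth.
#
# Emulates the shape of the experimental data the models are fitted to: ON
# and OFF switch percent-CAR series at 0 and 1 uM 4-OHT, ten observations
# each over a ten-day window, normalized to the global maximum. The shipped
# ground-truth parameter set is synthetic: it is NOT a published fitted
# optimum, only a documented parameterization with the qualitative behaviour
# the circuit is designed for.

#' Shipped synthetic ground-truth parameters
#'
#' A fixed, versioned reduced-model parameter set (all fitted values inside
#' the unit search interval) chosen so that at 1 uM the ON switch rises to a
#' high plateau within about ten days, the OFF switch falls correspondingly,
#' and the uninduced condition shows a small basal rise through the leak
#' pathway. Changing these values is a breaking change gated by tests.
#'
#' @return A [reduced_parameters()] object.
#' @export
default_truth <- function() {
  reduced_parameters(
    alpha_a = 0.9, alpha_b = 0.25, beta_p = 0.1, beta_d = 0.08,
    K_a = 0.9, K_b = 0.01,
    k1 = 0.9, k2 = 0.85, k3 = 0.8, k4 = 0.75, k_r = 0.03, delta = 0.1,
    alpha_d = 0, vbar = 0.3)
}

#' Configuration of the synthetic-data generator
#'
#' @param truth Ground-truth [reduced_parameters()]; default
#'   [default_truth()].
#' @param doses 4-OHT doses in uM; default `c(0, 1)`.
#' @param days Observation days within the ten-day window; default `1:10`
#'   (the true sampling days of the underlying experiments are a
#'   convention, not a published fact).
#' @param noise_sd Standard deviation of the additive Gaussian observation
#'   noise, in percentage points; default 3.
#' @param seed Integer seed for reproducible noise.
#' @param apply_global_max_normalization Rescale so the largest generated
#'   value maps to 100 (default `TRUE`).
#' @param dose_map A [dose_condition()] carrying the calibration constants.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(truth = default_truth(), doses = c(0, 1),
                             days = 1:10, noise_sd = 3, seed = 1L,
                             apply_global_max_normalization = TRUE,
                             dose_map = dose_condition(1)) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(days < 0 | days > 10)) stop("observation days must lie in [0, 10]")
  structure(list(truth = truth, doses = doses, days = days,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 apply_global_max_normalization = apply_global_max_normalization,
                 dose_map = dose_map),
            class = "synthetic_config")
}

#' Generate the four synthetic time-course datasets
#'
#' Simulates the reduced model at each dose, evaluates the ON and OFF
#' observables at the observation days, adds independent Gaussian noise,
#' clips to \[0, 100\], and optionally applies the global-maximum
#' normalization. The returned object carries the ground-truth record needed
#' for parameter-recovery experiments.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_timecourses` with `datasets` (tidy
#'   tibble: switch, dose_uM, day, percent_car) and `truth` (parameters,
#'   noiseless values, seed, config).
#' @export
generate_datasets <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  clean <- simulate_percent_grid(config$truth, doses = config$doses,
                                 days = config$days,
                                 dose_map = config$dose_map)
  data <- clean
  if (config$noise_sd > 0) {
    set.seed(config$seed)
    data$percent_car <- data$percent_car +
      stats::rnorm(nrow(data), sd = config$noise_sd)
    data$percent_car <- pmin(pmax(data$percent_car, 0), 100)
  }
  if (config$apply_global_max_normalization) {
    data <- normalize_to_global_max(data)
  }
  structure(list(datasets = data,
                 truth = list(parameters = config$truth,
                              noiseless = clean,
                              seed = config$seed,
                              config = config)),
            class = "synthetic_timecourses")
}

#' @export
print.synthetic_timecourses <- function(x, ...) {
  cat("<synthetic_timecourses>", nrow(x$datasets), "observations;",
      "noise_sd =", x$truth$config$noise_sd, "\n")
  print(utils::head(x$datasets, 4))
  invisible(x)
}
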