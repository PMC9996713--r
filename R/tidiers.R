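# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a GA fit
#'
#' @param x A `switch_fit`.
#' @param ... Unused.
#' @return Tibble with one row per fitted rate constant (`term`,
#'   `estimate`).
#' @method tidy switch_fit
#' @export
tidy.switch_fit <- function(x, ...) {
  tibble::tibble(term = names(x$parameters),
                 estimate = as.numeric(x$parameters))
}

#' One-row summary of a GA fit
#'
#' @param x A `switch_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `error`, `evaluations`,
#'   `failed_evaluations`, `generations`, `seed`.
#' @method glance switch_fit
#' @export
glance.switch_fit <- function(x, ...) {
  tibble::tibble(model = x$model, error = x$error,
                 evaluations = x$evaluations,
                 failed_evaluations = x$failed_evaluations,
                 generations = x$config$generations, seed = x$seed)
}

#' Tidy an ABC-SMC result
#'
#' Weighted posterior quantiles of the final completed population.
#'
#' @param x An `abc_smc_result`.
#' @param population Population index (default the last completed one).
#' @param ... Unused.
#' @return Quantile tibble from [posterior_summary()].
#' @method tidy abc_smc_result
#' @export
tidy.abc_smc_result <- function(x, population = length(x$populations), ...) {
  posterior_summary(x$populations[[population]])$quantiles
}

#' One-row summary of an ABC-SMC run
#'
#' @param x An `abc_smc_result`.
#' @param ... Unused.
#' @return Tibble with `n_populations`, `reached_epsilon`,
#'   `terminated_early`, `final_acceptance_percent`, `seed`.
#' @method glance abc_smc_result
#' @export
glance.abc_smc_result <- function(x, ...) {
  last <- x$populations[[length(x$populations)]]
  tibble::tibble(n_populations = length(x$populations),
                 reached_epsilon = x$reached_epsilon,
                 terminated_early = x$terminated_early,
                 final_acceptance_percent = last$acceptance_percent,
                 seed = x$seed)
}
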