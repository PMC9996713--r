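# Reading and writing time courses, fit results, ABC populations, and
# run-provenance blocks.

#' Validate a tidy four-dataset time-course table
#'
#' @param data Data frame with columns `switch`, `dose_uM`, `day`,
#'   `percent_car`.
#' @param expected_points Required observations per (switch, dose) series;
#'   `NULL` disables the count check.
#' @return The data, invisibly, if valid; otherwise an error naming the
#'   offending series or row.
#' @export
validate_timecourses <- function(data, expected_points = NULL) {
  need <- c("switch", "dose_uM", "day", "percent_car")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad_sw <- which(!data$switch %in% c("ON", "OFF"))
  if (length(bad_sw)) {
    stop("row ", bad_sw[1], ": switch must be \"ON\" or \"OFF\", got \"",
         data$switch[bad_sw[1]], "\"")
  }
  for (col in c("dose_uM", "day", "percent_car")) {
    bad <- which(!is.finite(data[[col]]))
    if (length(bad)) stop("row ", bad[1], ": non-numeric ", col)
  }
  bad_pct <- which(data$percent_car < 0 | data$percent_car > 100)
  if (length(bad_pct)) {
    stop("row ", bad_pct[1], ": percent_car outside [0, 100]")
  }
  doses <- sort(unique(data$dose_uM))
  for (sw in c("ON", "OFF")) {
    for (d in doses) {
      sub <- data[data$switch == sw & data$dose_uM == d, ]
      if (nrow(sub) == 0) {
        stop("missing time-course series for (", sw, ", ", d, " uM)")
      }
      if (any(duplicated(sub$day))) {
        stop("duplicated day in series (", sw, ", ", d, " uM)")
      }
      if (!is.null(expected_points) && nrow(sub) != expected_points) {
        stop("series (", sw, ", ", d, " uM) has ", nrow(sub),
             " points, expected ", expected_points)
      }
    }
  }
  invisible(data)
}

#' Read the four time-course datasets from CSV
#'
#' Expects the tidy schema `switch,dose_uM,day,percent_car`, groups rows
#' into the (orientation x dose) series, and validates coverage.
#'
#' @param path CSV file path.
#' @param expected_points Required points per series (default 10; `NULL`
#'   disables).
#' @return A validated tibble.
#' @export
read_timecourses <- function(path, expected_points = 10) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  data <- tibble::as_tibble(raw)
  for (col in c("dose_uM", "day", "percent_car")) {
    if (col %in% names(data)) data[[col]] <- suppressWarnings(
      as.numeric(data[[col]]))
  }
  validate_timecourses(data, expected_points = expected_points)
  dplyr::arrange(data, .data$switch, .data$dose_uM, .data$day)
}

#' Write time-course datasets to CSV
#'
#' @param data Tidy time-course tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(data, path) {
  utils::write.csv(data[, c("switch", "dose_uM", "day", "percent_car")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @keywords internal
#' Stable 32-bit FNV-1a hash of a configuration object (via its canonical
#' JSON rendering); changes iff the configuration content changes.
config_hash <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  bytes <- as.integer(charToRaw(as.character(txt)))
  # polynomial rolling hash kept in double precision below 2^31
  h <- 0
  for (b in bytes) h <- (h * 131 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

#' @keywords internal
provenance_block <- function(seed, config) {
  list(seed = seed, config_hash = config_hash(config),
       package_version = as.character(utils::packageVersion("flpswitch")))
}

#' Write a GA fit result to JSON
#'
#' @param fit A `switch_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(model = fit$model,
              parameters = as.list(fit$parameters),
              error = fit$error,
              evaluations = fit$evaluations,
              failed_evaluations = fit$failed_evaluations,
              residuals = fit$residuals,
              history = fit$history,
              provenance = provenance_block(fit$seed, fit$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a GA fit result written by [write_fit_json()]
#'
#' @param path JSON path.
#' @return A list mirroring the `switch_fit` fields.
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$parameters <- unlist(obj$parameters)
  obj$residuals <- tibble::as_tibble(obj$residuals)
  obj
}

#' Write an ABC-SMC result to a directory
#'
#' Emits one CSV per population (particles, importance weights, errors) and
#' an acceptance-log CSV (`epsilon`, `particles_assessed`,
#' `particles_accepted_percent`).
#'
#' @param result An `abc_smc_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_abc_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(result$populations)) {
    pop <- result$populations[[i]]
    df <- pop$particles
    df$weight <- pop$weights
    df$error <- pop$errors
    utils::write.csv(df, file.path(dir, sprintf("population_%02d.csv", i)),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(result$log, file.path(dir, "acceptance_log.csv"),
                   row.names = FALSE, quote = FALSE)
  prov <- provenance_block(result$seed, result$config)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
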