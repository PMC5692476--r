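#' Read folding transients from CSV
#'
#' Expects a UTF-8 CSV with header `time_s, signal, condition, replicate,
#' batch` (the last three optional). Time must be strictly increasing
#' within each (condition, replicate, batch) trace.
#'
#' @param path CSV path.
#' @return A validated transient tibble.
#' @export
read_transients_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_s", "signal") %in% names(data))) {
    abort_input("CSV must have header columns `time_s` and `signal`")
  }
  if (!is.numeric(data$time_s) || !is.numeric(data$signal)) {
    abort_input("`time_s` and `signal` must parse as numbers")
  }
  check_transient_tbl(data)
}

#' Read a binding titration from CSV
#'
#' Expects header `ligand_M, signal`.
#'
#' @param path CSV path.
#' @return A tibble with `ligand_M` and `signal`.
#' @export
read_titration_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("ligand_M", "signal") %in% names(data))) {
    abort_input("CSV must have header columns `ligand_M` and `signal`")
  }
  as_tibble(data)
}

#' Write analysis results as schema-versioned JSON
#'
#' Serializes fit results (or any list / data frame) to JSON with a schema
#' version stamp so downstream consumers can detect format changes. Rates
#' are in per second, times in seconds, lengths in Angstrom.
#'
#' @param results A list, data frame, or foldkit fit object (tidied via
#'   [tidy()] where available).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  if (inherits(results, c("foldkit_expfit", "foldkit_hillfit",
                          "foldkit_membrane_profile"))) {
    results <- list(parameters = tidy(results), summary = glance_or_null(results))
  }
  payload <- list(schema_version = "1.0",
                  package = "foldkit",
                  results = results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

glance_or_null <- function(x) {
  tryCatch(glance(x), error = function(e) NULL)
}

#' Read back a results JSON file
#'
#' @param path JSON path written by [write_results_json()].
#' @return The parsed payload list.
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
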