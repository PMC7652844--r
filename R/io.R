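# Plain-text interchange: feature tables as CSV, reports and artifact logs
# as JSON, configs as JSON.

#' Write a feature table as CSV
#' @param table A `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV
#' @param path CSV written by [write_feature_table()].
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Serialize a cleaning report to JSON
#' @param report A `cleaning_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a simulation config from JSON
#'
#' The JSON object may set any [sim_config()] argument; `artifact_spec` is
#' itself an object of [artifact_spec()] arguments.
#'
#' @param path JSON file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$artifact_spec)) {
    raw$artifact_spec <- do.call(artifact_spec, as.list(raw$artifact_spec))
  }
  if (!is.null(raw$band_amplitudes)) {
    raw$band_amplitudes <- unlist(raw$band_amplitudes)
  }
  do.call(sim_config, raw)
}

#' Read a cleaning config from JSON
#' @param path JSON file path; keys are [cleaning_config()] arguments.
#' @return A `cleaning_config`.
#' @export
read_cleaning_config <- function(path) {
  do.call(cleaning_config, jsonlite::read_json(path, simplifyVector = TRUE))
}
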