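#' Write a machine-readable evaluation report
#'
#' Serializes any collection of analysis results to a JSON-syntax text file
#' together with the configuration used and the package version. Keys are
#' stable and numbers are written at full precision, so re-running on
#' identical input and seed yields a byte-identical file.
#'
#' @param results Named list of result objects (tibbles, lists, scalars).
#' @param path Output file path.
#' @param config Named list recording the configuration used.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, config = list()) {
  payload <- list(
    tool = "screeneval",
    version = as.character(utils::packageVersion("screeneval")),
    config = config,
    results = results
  )
  json <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null", null = "null",
                           pretty = TRUE)
  ok <- tryCatch({
    suppressWarnings(writeLines(json, path))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write report to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Path to the JSON report.
#' @return The parsed report: list with `tool`, `version`, `config`,
#'   `results` (data-frame results come back as data frames).
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
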