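metric_cols <- c("ik_sys", "ik_late_dia", "ik_early_dia", "hr")

#' Validate a per-record metric table
#'
#' A metric table has one row per (subject, session) pair and columns
#' `subject_id`, `session`, `ik_sys`, `ik_late_dia`, `ik_early_dia`
#' (nJ s) and `hr` (bpm). Metric values must be non-negative when present.
#'
#' @param df A data frame.
#' @return The validated data frame (invisibly classed `metric_table`).
#' @export
as_metric_table <- function(df) {
  need <- c("subject_id", "session", metric_cols)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("metric table missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  key <- paste(df$subject_id, df$session, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject_id, session) keys in metric table",
         call. = FALSE)
  for (cl in metric_cols)
    if (any(df[[cl]] < 0, na.rm = TRUE))
      stop(sprintf("negative values in metric column '%s'", cl),
           call. = FALSE)
  class(df) <- c("metric_table", "data.frame")
  df
}

#' Write a metric table with a parameter sidecar
#'
#' Fixed column order, full double precision, deterministic byte output.
#' The resolved pipeline configuration is written alongside as
#' `<path>.params.json` so every results file carries its provenance.
#'
#' @param table A metric table (see [as_metric_table()]).
#' @param path Output CSV path.
#' @param params Named list of pipeline parameters for the sidecar
#'   (default [scg_config()]).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(table, path, params = scg_config()) {
  table <- as_metric_table(as.data.frame(table))
  df <- as.data.frame(table)[, c("subject_id", "session", metric_cols)]
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(package = "scgkinetics",
         version = as.character(utils::packageVersion("scgkinetics")),
         params = unclass(params)),
    paste0(path, ".params.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' Read a metric table written by [write_metrics()]
#'
#' @param path CSV path.
#' @return A validated `metric_table`.
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(subject_id = "character",
                                       session = "character"))
  as_metric_table(df)
}

#' Read and validate an at-home compliance table
#'
#' One row per patient with columns `age` (years), `expected_count` and
#' `completed_count` (non-negative integers). Over-compliance
#' (completed > expected) is allowed.
#'
#' @param path CSV path, or a data frame with the same columns.
#' @return A validated data frame classed `compliance_table`.
#' @export
read_compliance <- function(path) {
  df <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                                 call. = FALSE)
    utils::read.csv(path, check.names = FALSE)
  }
  need <- c("age", "expected_count", "completed_count")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("compliance table missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (any(df$age < 0) || any(df$expected_count < 0) ||
      any(df$completed_count < 0))
    stop("compliance table values must be non-negative", call. = FALSE)
  if (any(df$expected_count != round(df$expected_count)) ||
      any(df$completed_count != round(df$completed_count)))
    stop("recording counts must be integers", call. = FALSE)
  class(df) <- c("compliance_table", "data.frame")
  df
}
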