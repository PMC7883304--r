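# Table schemas and CSV I/O. Dialect: UTF-8, comma separator, header row,
# "." decimal, NA for missing values.

#' Column schemas for the pipeline's tables
#'
#' Each schema lists required columns, their types, and row-level checks
#' used by [validate_schema()].
#'
#' @format A named list of schema definitions.
#' @export
table_schemas <- list(
  fixations = list(
    columns = c(participant = "integer", visit = "character",
                phase = "character", trial = "integer",
                onset_ms = "numeric", duration_ms = "numeric",
                x = "numeric", y = "numeric", disgust_side = "character"),
    checks = list(
      "duration_ms must be positive" = function(df) df$duration_ms > 0,
      "onset_ms must be non-negative" = function(df) df$onset_ms >= 0,
      "disgust_side must be left/right" =
        function(df) df$disgust_side %in% c("left", "right"))
  ),
  dwell = list(
    columns = c(participant = "integer", visit = "character",
                phase = "character", trial = "integer",
                p_disgust = "numeric", p_neutral = "numeric",
                p_nonstim = "numeric", valid_fraction = "numeric",
                missing = "logical"),
    checks = list(
      "proportions must lie in [0, 1]" = function(df) {
        ok <- df$missing |
          (df$p_disgust >= 0 & df$p_disgust <= 1 &
             df$p_neutral >= 0 & df$p_neutral <= 1 &
             df$p_nonstim >= 0 & df$p_nonstim <= 1)
        ok
      },
      "proportions must sum to 1" = function(df) {
        df$missing |
          abs(df$p_disgust + df$p_neutral + df$p_nonstim - 1) < 1e-9
      },
      "valid_fraction must lie in [0, 1]" =
        function(df) df$valid_fraction >= 0 & df$valid_fraction <= 1)
  ),
  choices = list(
    columns = c(participant = "integer", visit = "character",
                phase = "character", trial = "integer",
                choice = "character", reward = "integer"),
    checks = list(
      "choice must be A/B" = function(df) df$choice %in% c("A", "B"),
      "reward must be 0/1" = function(df) df$reward %in% c(0L, 1L))
  ),
  self_report = list(
    columns = c(participant = "integer", visit = "character",
                phase = "character", category = "character",
                rating = "numeric"),
    checks = list(
      "rating must lie in [0, 100]" =
        function(df) df$rating >= 0 & df$rating <= 100)
  ),
  effects = list(
    columns = c(term = "character", beta = "numeric", ci_low = "numeric",
                ci_high = "numeric", z = "numeric", p = "numeric"),
    checks = list(
      "confidence interval must bracket beta" =
        function(df) df$ci_low <= df$beta & df$beta <= df$ci_high)
  )
)

#' Validate a table against a schema
#'
#' Checks required columns, coercible types, and the schema's row-level
#' invariants; missing columns and offending rows are named in the error.
#'
#' @param df Data frame to validate.
#' @param schema A schema name from [table_schemas] or a schema list.
#' @return The data frame, invisibly, if valid; otherwise an error listing
#'   every violation.
#' @export
validate_schema <- function(df, schema) {
  if (is.character(schema)) {
    if (!schema %in% names(table_schemas))
      stop(sprintf("unknown schema '%s'", schema), call. = FALSE)
    schema <- table_schemas[[schema]]
  }
  errs <- character(0)
  missing <- setdiff(names(schema$columns), names(df))
  if (length(missing))
    errs <- c(errs, sprintf("missing column(s): %s",
                            paste(missing, collapse = ", ")))
  if (!length(missing)) {
    for (nm in names(schema$columns)) {
      want <- schema$columns[[nm]]
      val <- df[[nm]]
      ok <- switch(want,
        integer = is.numeric(val) && all(is.na(val) | val == floor(val)),
        numeric = is.numeric(val),
        character = is.character(val) || is.factor(val),
        logical = is.logical(val))
      if (!ok) errs <- c(errs, sprintf("column '%s' is not %s", nm, want))
    }
    if (!length(errs)) {
      for (msg in names(schema$checks)) {
        ok <- schema$checks[[msg]](df)
        bad <- which(!ok | is.na(ok))
        if (length(bad))
          errs <- c(errs, sprintf("%s (rows %s)", msg,
                                  paste(utils::head(bad, 5L),
                                        collapse = ", ")))
      }
    }
  }
  if (length(errs))
    stop(paste(c("schema validation failed:", errs), collapse = "\n  "),
         call. = FALSE)
  invisible(df)
}

#' Write a pipeline table as CSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @param schema Optional schema name to validate against before writing.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path, schema = NULL) {
  if (!is.null(schema)) validate_schema(df, schema)
  write.csv(df, path, row.names = FALSE, na = "NA", fileEncoding = "UTF-8",
            quote = FALSE)
  invisible(path)
}

#' Read a pipeline table from CSV
#'
#' @param path Input path.
#' @param schema Optional schema name to validate against after reading.
#' @return The data frame.
#' @export
read_table_csv <- function(path, schema = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if ("missing" %in% names(df)) df$missing <- as.logical(df$missing)
  if (!is.null(schema)) validate_schema(df, schema)
  df
}

#' Read a pipeline configuration from JSON
#'
#' Missing fields fall back to the generators' defaults. Fields mirror the
#' constructor arguments of [study_design()], [gaze_sim_config()],
#' [rl_sim_config()] and [aoi_layout()], plus `out_dir`, `seed`, `alpha`,
#' `max_missing` and `n_starts`.
#'
#' @param path Path to a JSON file.
#' @return A named list of class `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "pipeline_config")
}
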