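# File schemas (versioned):
#   event logs v1:  participant_id,trial_id,condition_id,button,t_on,t_off,trial_duration
#   metadata   v1:  participant_id,group,age,seed
#   catalog    v1:  trial,condition_id,variant,eye,position,orientation
# All files are UTF-8 comma-delimited text with a header row, '.' decimal
# separator, and empty cells for missing values.

log_schema <- c(
  "participant_id", "trial_id", "condition_id",
  "button", "t_on", "t_off", "trial_duration"
)
metadata_schema <- c("participant_id", "group", "age", "seed")

check_schema <- function(df, schema, what) {
  missing_cols <- setdiff(schema, names(df))
  if (length(missing_cols)) {
    abort(sprintf(
      "%s header is missing column(s): %s", what,
      paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(df)
}

#' Read an event-log file
#'
#' @param path Path to a delimited text file with header
#'   `participant_id,trial_id,condition_id,button,t_on,t_off,trial_duration`.
#' @return A tibble of press intervals. A `(participant_id, trial_id)` pair
#'   mapped to more than one `condition_id` is rejected.
#' @export
read_event_logs <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  # a missing schema column is reported below as a schema error, not as a
  # readr unmatched-parser warning
  logs <- withCallingHandlers(
    readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      trial_id = readr::col_integer(),
      condition_id = readr::col_character(),
      button = readr::col_character(),
      t_on = readr::col_double(),
      t_off = readr::col_double(),
      trial_duration = readr::col_double(),
      .default = readr::col_guess()
    ),
    show_col_types = FALSE
    ),
    warning = function(w) {
      if (grepl("don't match the column names", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  check_schema(logs, log_schema, "event log")
  key <- dplyr::distinct(logs, .data$participant_id, .data$trial_id, .data$condition_id)
  dup <- key |>
    dplyr::count(.data$participant_id, .data$trial_id) |>
    filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf(
      "duplicate (participant, trial) with conflicting conditions: %s",
      paste(sprintf("(%s, %s)", dup$participant_id, dup$trial_id), collapse = ", ")
    ))
  }
  logs
}

#' Write an event-log file
#'
#' @param logs A flat event-log tibble (see [read_event_logs()] for the
#'   schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_logs <- function(logs, path) {
  check_schema(logs, log_schema, "event log")
  readr::write_csv(logs[log_schema], path)
  invisible(path)
}

#' Read a cohort metadata file
#'
#' @param path Path to a delimited text file with header
#'   `participant_id,group,age,seed`.
#' @return A tibble; duplicate participant ids are rejected.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  meta <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      group = readr::col_character(),
      age = readr::col_double(),
      seed = readr::col_double()
    ),
    show_col_types = FALSE
  )
  check_schema(meta, metadata_schema, "metadata")
  dup <- unique(meta$participant_id[duplicated(meta$participant_id)])
  if (length(dup)) {
    abort(sprintf("duplicate participant_id: %s", paste(dup, collapse = ", ")))
  }
  bad <- setdiff(unique(meta$group), group_levels)
  if (length(bad)) {
    abort(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")))
  }
  meta
}

#' @rdname read_metadata
#' @param metadata A metadata tibble.
#' @export
write_metadata <- function(metadata, path) {
  check_schema(metadata, metadata_schema, "metadata")
  readr::write_csv(metadata[metadata_schema], path)
  invisible(path)
}

#' Read/write a condition catalog file
#'
#' @param path File path.
#' @return [read_condition_catalog()] returns the catalog tibble.
#' @export
read_condition_catalog <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  cat_schema <- c("trial", "condition_id", "variant", "eye", "position", "orientation")
  x <- readr::read_csv(path, show_col_types = FALSE, col_types = readr::cols(
    trial = readr::col_integer(), variant = readr::col_integer(),
    .default = readr::col_character()
  ))
  check_schema(x, cat_schema, "condition catalog")
  x
}

#' @rdname read_condition_catalog
#' @param catalog A condition catalog from [build_condition_set()].
#' @export
write_condition_catalog <- function(catalog, path) {
  readr::write_csv(catalog, path)
  invisible(path)
}

#' Read/write a run configuration file (YAML)
#'
#' @param path File path.
#' @return [read_run_config()] returns a validated [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- unclass(config)
  # an absent tau_gap reads back as the default (Inf); YAML has no portable Inf
  if (is.infinite(vals$tau_gap)) vals$tau_gap <- NULL
  yaml::write_yaml(vals, path)
  invisible(path)
}
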