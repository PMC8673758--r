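#' Read and write session logs
#'
#' Session logs are exchanged as flat CSV files, one row per trial, with
#' the subject/condition/seed metadata repeated on every row, and as a
#' JSON mirror for round-trip fidelity.
#'
#' @param session a [session_log()].
#' @param path output file path.
#' @return The path, invisibly (writers); a [session_log()] (readers).
#' @export
write_session_log <- function(session, path) {
  stopifnot(inherits(session, "session_log"))
  df <- session$trials
  df$subject <- session$subject
  df$condition <- session$condition
  df$seed <- session$seed
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  meta_cols <- c("subject", "condition", "seed")
  session_log(trials = df[, setdiff(names(df), meta_cols)],
              subject = as.character(df$subject[1]),
              condition = df$condition[1],
              seed = df$seed[1])
}

#' @rdname write_session_log
#' @export
write_session_json <- function(session, path) {
  stopifnot(inherits(session, "session_log"))
  jsonlite::write_json(list(subject = session$subject,
                            condition = session$condition,
                            seed = session$seed,
                            trials = session$trials),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  session_log(trials = obj$trials, subject = as.character(obj$subject),
              condition = obj$condition, seed = obj$seed)
}

#' Read and write reward schedules
#'
#' Schedules are stored as CSV with one row per trial and columns `pA`,
#' `pB`, `pC`.
#'
#' @param schedule a `reward_schedule` matrix.
#' @param path file path.
#' @return The path, invisibly (writer); a `reward_schedule` (reader).
#' @export
write_schedule <- function(schedule, path) {
  write.csv(as.data.frame(unclass(schedule)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("pA", "pB", "pC") %in% names(df)))
  structure(as.matrix(df[, c("pA", "pB", "pC")]), class = "reward_schedule")
}

#' Read and write schedule configurations
#'
#' A [schedule_config()] round-trips through a structured key/value file:
#' YAML when the path ends in `.yaml`/`.yml`, JSON otherwise.
#'
#' @param config a [schedule_config()].
#' @param path file path.
#' @return The path, invisibly (writer); a [schedule_config()] (reader).
#' @export
write_schedule_config <- function(config, path) {
  stopifnot(inherits(config, "schedule_config"))
  obj <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    writeLines(yaml::as.yaml(obj), path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_schedule_config
#' @export
read_schedule_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(obj$option_ranges) && is.list(obj$option_ranges)) {
    obj$option_ranges <- lapply(obj$option_ranges, as.numeric)
  }
  num <- intersect(c("reversal_fraction", "reversal_width",
                     "drift_smoothness", "drift_amplitude",
                     "max_shared_variance"), names(obj))
  obj[num] <- lapply(obj[num], as.numeric)
  do.call(schedule_config, obj)
}
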