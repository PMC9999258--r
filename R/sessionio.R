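# Persistence and exchange: session records as JSON / JSON-lines
# archives, per-day summary reports, and stream serialization (JSON-lines
# frames and wide CSV). All formats are plain text by design.

SCHEMA_VERSION <- "1.0"

#' A persisted training-session record
#'
#' @param patient_id Pseudonymous patient identifier.
#' @param timestamp Session date-time (POSIXct or ISO-8601 string).
#' @param prescription A \code{\link{prescription_item}}.
#' @param result A \code{session_result} from \code{\link{score_session}}.
#' @param software_version Software version string.
#' @param schema_version Record schema version (defaults to the current
#'   one).
#' @return An object of class \code{session_record}.
#' @export
session_record <- function(patient_id, timestamp, prescription, result,
                           software_version = "0.1.0",
                           schema_version = SCHEMA_VERSION) {
  rec <- structure(
    list(patient_id = patient_id,
         timestamp = format(as.POSIXct(timestamp, tz = "UTC"),
                            "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
         prescription = prescription, result = result,
         software_version = software_version,
         schema_version = schema_version),
    class = "session_record")
  validate_session_record(rec)
  rec
}

validate_session_record <- function(rec) {
  bad <- character(0)
  if (is.null(rec$patient_id) || !nzchar(rec$patient_id)) {
    bad <- c(bad, "patient_id")
  }
  if (is.null(rec$timestamp) ||
      !grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}", rec$timestamp)) {
    bad <- c(bad, "timestamp")
  }
  if (is.null(rec$prescription) ||
      !inherits(rec$prescription, "prescription_item")) {
    bad <- c(bad, "prescription")
  }
  if (is.null(rec$result) || !inherits(rec$result, "session_result")) {
    bad <- c(bad, "result")
  }
  if (is.null(rec$schema_version) || !nzchar(rec$schema_version)) {
    bad <- c(bad, "schema_version")
  }
  if (length(bad)) {
    stop_param("invalid session record; offending fields: %s",
               paste(bad, collapse = ", "))
  }
  invisible(rec)
}

record_to_list <- function(rec) {
  list(
    patient_id = rec$patient_id,
    timestamp = rec$timestamp,
    prescription = unclass(rec$prescription),
    result = list(
      exercise_id = rec$result$exercise_id,
      difficulty = rec$result$difficulty,
      rep_results = rec$result$rep_results,
      valid_count = rec$result$valid_count,
      game_score = rec$result$game_score,
      session_score = rec$result$session_score
    ),
    software_version = rec$software_version,
    schema_version = rec$schema_version
  )
}

list_to_record <- function(x) {
  pres <- do.call(prescription_item, x$prescription[
    c("exercise_id", "difficulty", "target_reps", "session_minutes",
      "sessions_per_day")])
  rr <- as.data.frame(x$result$rep_results)
  if (nrow(rr) == 0) {
    rr <- data.frame(rep_index = integer(0), amp = numeric(0),
                     mean = numeric(0), rms = numeric(0),
                     jerk = numeric(0), strength = numeric(0),
                     similarity = numeric(0), valid = logical(0))
  }
  res <- structure(
    list(exercise_id = x$result$exercise_id,
         difficulty = x$result$difficulty,
         rep_results = rr,
         valid_count = as.integer(x$result$valid_count),
         game_score = as.integer(x$result$game_score),
         session_score = as.numeric(x$result$session_score)),
    class = "session_result")
  session_record(x$patient_id, x$timestamp, pres, res,
                 software_version = x$software_version,
                 schema_version = x$schema_version)
}

#' Write one session record to a JSON file
#'
#' @param record A \code{\link{session_record}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_session <- function(record, path) {
  validate_session_record(record)
  jsonlite::write_json(record_to_list(record), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read one session record from a JSON file
#'
#' @param path Path written by \code{\link{write_session}}.
#' @return A \code{session_record}.
#' @export
read_session <- function(path) {
  list_to_record(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Append session records to a JSON-lines archive
#'
#' @param records List of \code{session_record} objects.
#' @param path Archive path; records are appended, one JSON document per
#'   line.
#' @return The path, invisibly.
#' @export
append_session_archive <- function(records, path) {
  if (inherits(records, "session_record")) records <- list(records)
  lines <- vapply(records, function(r) {
    validate_session_record(r)
    as.character(jsonlite::toJSON(record_to_list(r), auto_unbox = TRUE,
                                  digits = NA))
  }, character(1))
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read all session records from a JSON-lines archive
#'
#' @param path Archive path.
#' @return List of \code{session_record} objects in file order.
#' @export
read_session_archive <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    list_to_record(jsonlite::fromJSON(l, simplifyVector = TRUE))
  })
}

#' Per-day training report
#'
#' Aggregates session records into one row per (patient, day): number of
#' sessions, total valid repetitions, mean session score, and the
#' difficulty trajectory (difficulties seen that day, in session order).
#'
#' @param records List of \code{session_record} objects.
#' @param path Optional CSV output path.
#' @return Data.frame with columns \code{patient_id}, \code{date},
#'   \code{sessions}, \code{valid_count}, \code{mean_session_score},
#'   \code{difficulty}. Empty input gives an empty table with the same
#'   header.
#' @export
session_report <- function(records, path = NULL) {
  if (length(records) == 0) {
    df <- data.frame(patient_id = character(0), date = character(0),
                     sessions = integer(0), valid_count = integer(0),
                     mean_session_score = numeric(0),
                     difficulty = character(0))
  } else {
    rows <- data.frame(
      patient_id = vapply(records, `[[`, character(1), "patient_id"),
      date = substr(vapply(records, `[[`, character(1), "timestamp"), 1, 10),
      valid_count = vapply(records, function(r) r$result$valid_count,
                           numeric(1)),
      session_score = vapply(records, function(r) r$result$session_score,
                             numeric(1)),
      difficulty = vapply(records, function(r) r$result$difficulty,
                          character(1)),
      stringsAsFactors = FALSE
    )
    sp <- split(rows, list(rows$patient_id, rows$date), drop = TRUE)
    df <- do.call(rbind, lapply(sp, function(g) {
      data.frame(patient_id = g$patient_id[1], date = g$date[1],
                 sessions = nrow(g),
                 valid_count = as.integer(sum(g$valid_count)),
                 mean_session_score = mean(g$session_score),
                 difficulty = paste(g$difficulty, collapse = ">"),
                 stringsAsFactors = FALSE)
    }))
    df <- df[order(df$patient_id, df$date), , drop = FALSE]
    rownames(df) <- NULL
  }
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Write a motion stream as JSON-lines (one frame per line)
#'
#' @param stream A \code{motion_stream}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_stream_jsonl <- function(stream, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  header <- list(type = "header", exercise_id = stream$exercise_id,
                 segment = stream$segment, fs = stream$fs,
                 primary_device = stream$primary_device,
                 ground_truth = stream$ground_truth)
  writeLines(as.character(jsonlite::toJSON(header, auto_unbox = TRUE,
                                           digits = NA)), con)
  for (d in names(stream$devices)) {
    fr <- stream$devices[[d]]
    for (i in seq_len(nrow(fr))) {
      rec <- c(list(type = "frame", device_role = d), as.list(fr[i, ]))
      writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                               digits = NA)), con)
    }
  }
  invisible(path)
}

#' Read a motion stream from JSON-lines
#'
#' @param path Path written by \code{\link{write_stream_jsonl}}.
#' @return A \code{motion_stream} (without generator parameters).
#' @export
read_stream_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  header <- recs[[1]]
  if (!identical(header$type, "header")) {
    stop_param("stream file must start with a header line")
  }
  frames <- recs[-1]
  roles <- vapply(frames, `[[`, character(1), "device_role")
  devices <- lapply(split(frames, roles), function(rows) {
    do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r[setdiff(names(r), c("type", "device_role"))])
    }))
  })
  gt <- as.data.frame(header$ground_truth)
  if (nrow(gt) == 0) {
    gt <- data.frame(rep_index = integer(0), start_index = integer(0),
                     end_index = integer(0), t_start = numeric(0),
                     t_end = numeric(0), amplitude = numeric(0),
                     intended_valid = logical(0))
  }
  structure(
    list(exercise_id = header$exercise_id, segment = header$segment,
         fs = header$fs, primary_device = header$primary_device,
         devices = devices[unique(roles)], ground_truth = gt,
         params = NULL),
    class = "motion_stream"
  )
}

#' Write a motion stream as a wide CSV (one row per timestamp)
#'
#' Columns are device-prefixed channel names, e.g.
#' \code{upper_arm_ax}.
#'
#' @param stream A \code{motion_stream}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_stream_csv <- function(stream, path) {
  out <- data.frame(t = stream$devices[[1]]$t)
  for (d in names(stream$devices)) {
    fr <- stream$devices[[d]]
    cols <- setdiff(names(fr), "t")
    add <- fr[, cols, drop = FALSE]
    names(add) <- paste(d, cols, sep = "_")
    out <- cbind(out, add)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
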