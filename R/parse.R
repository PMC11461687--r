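## Column schemas of the two RTLS log files (comma separated, header row,
## ISO-8601 timestamps at minute or second resolution).
.patient_cols <- c("patient_id", "visit_start", "visit_end",
                   "move_start", "move_end", "room_name", "room_id")
.resource_cols <- c("resource_id", "resource_type", "room_name", "room_type",
                    "start", "end")
.patient_ts <- c("visit_start", "visit_end", "move_start", "move_end")
.resource_ts <- c("start", "end")

## Vectorized ISO-8601 parser; names the file/column and the 1-based data row
## of the first unparseable value.
parse_timestamps <- function(x, col, file) {
  x0 <- sub("T", " ", trimws(as.character(x)), fixed = TRUE)
  out <- as.POSIXct(x0, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  short <- is.na(out)
  if (any(short))
    out[short] <- as.POSIXct(x0[short], tz = "UTC", format = "%Y-%m-%d %H:%M")
  bad <- which(is.na(out) & !is.na(x) & nzchar(x0))
  if (length(bad))
    stop_cf("%s: unparseable timestamp '%s' in column '%s' at data row %d",
            file, x[bad[1]], col, bad[1])
  out
}

#' Parse patient and resource RTLS logs
#'
#' Reads the two delimited RTLS log files: the patient log (one row per visit
#' activity of a patient in a room: `patient_id`, `visit_start`, `visit_end`,
#' `move_start` (entry into the room), `move_end` (leaving the room),
#' `room_name`, `room_id`) and the resource log (one row per resource stay in
#' a room: `resource_id`, `resource_type`, `room_name`, `room_type`, `start`,
#' `end`).
#'
#' Records that cannot belong to a valid visit are dropped rather than
#' repaired: rows with inverted intervals (`move_end < move_start`,
#' `end < start`) and rows with missing identifiers. Counts of dropped rows
#' are returned in a cleaning report. A missing mandatory column raises a
#' schema error naming the column; an unparseable timestamp raises a row-level
#' error with the data row number.
#'
#' @param patient_log path to the patient log CSV.
#' @param resource_log path to the resource log CSV.
#' @return a list with `patient_events` and `resource_events` (data.tables
#'   sorted by id and start time, timestamps as POSIXct UTC) and `cleaning`,
#'   a list of dropped-row counts by reason.
#' @seealso [extract_activities()], [generate_synthetic_rtls()]
#' @export
parse_rtls_logs <- function(patient_log, resource_log) {
  for (f in c(patient_log, resource_log))
    if (!file.exists(f)) stop_cf("log file not found: %s", f)

  pe <- data.table::fread(patient_log, colClasses = "character")
  re <- data.table::fread(resource_log, colClasses = "character")
  miss_p <- setdiff(.patient_cols, names(pe))
  if (length(miss_p))
    stop_cf("patient log %s: missing mandatory column '%s'",
            patient_log, miss_p[1])
  miss_r <- setdiff(.resource_cols, names(re))
  if (length(miss_r))
    stop_cf("resource log %s: missing mandatory column '%s'",
            resource_log, miss_r[1])

  for (cc in .patient_ts)
    data.table::set(pe, j = cc, value = parse_timestamps(pe[[cc]], cc, patient_log))
  for (cc in .resource_ts)
    data.table::set(re, j = cc, value = parse_timestamps(re[[cc]], cc, resource_log))

  cleaning <- list()
  if (nrow(pe)) {
    bad_id <- is.na(pe$patient_id) | !nzchar(pe$patient_id)
    bad_iv <- !bad_id & (is.na(pe$move_start) | is.na(pe$move_end) |
                           pe$move_end < pe$move_start)
    cleaning$patient_missing_id <- sum(bad_id)
    cleaning$patient_inverted_interval <- sum(bad_iv)
    pe <- pe[!(bad_id | bad_iv)]
  } else {
    cleaning$patient_missing_id <- 0L
    cleaning$patient_inverted_interval <- 0L
  }
  if (nrow(re)) {
    bad_id <- is.na(re$resource_id) | !nzchar(re$resource_id)
    bad_iv <- !bad_id & (is.na(re$start) | is.na(re$end) | re$end < re$start)
    cleaning$resource_missing_id <- sum(bad_id)
    cleaning$resource_inverted_interval <- sum(bad_iv)
    re <- re[!(bad_id | bad_iv)]
  } else {
    cleaning$resource_missing_id <- 0L
    cleaning$resource_inverted_interval <- 0L
  }
  cleaning$patient_rows_kept <- nrow(pe)
  cleaning$resource_rows_kept <- nrow(re)

  data.table::setorder(pe, patient_id, move_start)
  data.table::setorder(re, resource_id, start)
  list(patient_events = pe[], resource_events = re[], cleaning = cleaning)
}
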