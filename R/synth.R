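#' Generate synthetic RTLS logs from pathway profiles
#'
#' Emulates the two RTLS log schemas so that the mining pipeline can be
#' exercised and validated without access to proprietary clinic data. For
#' each visit a pathway is sampled by its occurrence proportion, per-activity
#' durations are drawn from the moment-fitted log-normal distributions
#' (rounded to integer minutes, at least 1), and consistent patient and
#' resource co-location rows are emitted: each activity takes place in its
#' own exam room with the required resource unit(s) present for exactly the
#' activity span, so that [extract_activities()] followed by
#' [group_pathways()] recovers the generating pathways.
#'
#' Patients arrive at fixed intervals; activities within a visit are
#' back-to-back (the generator emulates observed co-location, not clinic
#' congestion). The output is byte-deterministic under a fixed seed.
#'
#' @param profiles a `careflow_profiles` object.
#' @param n_visits number of visits to generate (>= 1).
#' @param arrival_interval minutes between consecutive visit starts
#'   (default 10).
#' @param seed integer seed.
#' @param base_time POSIXct (UTC) timestamp of the first arrival.
#' @param units_per_type number of synthetic resource unit ids cycled through
#'   per resource type (default 3).
#' @return a list with `patient_log` and `resource_log` (data.tables in the
#'   RTLS schemas, POSIXct timestamps) and `path_ids`, the integer pathway id
#'   sampled for each visit.
#' @seealso [write_rtls_logs()], [parse_rtls_logs()]
#' @export
generate_synthetic_rtls <- function(profiles, n_visits, arrival_interval = 10,
                                    seed = 1L,
                                    base_time = as.POSIXct("2020-01-06 08:00:00",
                                                           tz = "UTC"),
                                    units_per_type = 3L) {
  stopifnot(inherits(profiles, "careflow_profiles"))
  if (!is_count(n_visits) || n_visits < 1)
    stop_cf("n_visits must be a positive integer")
  if (!is_count(arrival_interval) || arrival_interval < 1)
    stop_cf("arrival_interval must be a positive integer (minutes)")

  props <- vapply(profiles, `[[`, numeric(1), "proportion")
  with_seed(seed, {
    pick <- sample.int(length(profiles), n_visits, replace = TRUE, prob = props)
    ## per-visit step durations, drawn profile-by-profile for vectorization
    steps_of <- vapply(profiles, function(p) length(p$activity_sequence), 1L)
    dur <- matrix(NA_real_, nrow = n_visits, ncol = max(steps_of))
    for (k in seq_along(profiles)) {
      rows <- which(pick == k)
      if (!length(rows)) next
      p <- profiles[[k]]
      for (s in seq_along(p$activity_sequence)) {
        par <- lognormal_from_moments(p$duration_mean[s], p$duration_variance[s])
        dur[rows, s] <- pmax(1, round(sample_lognormal(length(rows), par)))
      }
    }
    NULL
  })

  n_steps <- vapply(profiles[pick], function(p) length(p$activity_sequence), 1L)
  visit <- rep(seq_len(n_visits), n_steps)
  step <- unlist(lapply(n_steps, seq_len), use.names = FALSE)
  d <- dur[cbind(visit, step)]
  arrive <- (visit - 1) * arrival_interval
  ## cumulative offsets of back-to-back activities within each visit
  cum <- unlist(lapply(split(d, visit), function(x) cumsum(c(0, x[-length(x)]))),
                use.names = FALSE)
  s_min <- arrive + cum
  e_min <- s_min + d

  labels <- unlist(lapply(profiles[pick], `[[`, "activity_sequence"),
                   use.names = FALSE)
  patient_id <- sprintf("P%06d", visit)
  room_id <- sprintf("R%06d_%d", visit, step)
  room_name <- sprintf("Exam %06d-%d", visit, step)
  visit_len <- vapply(split(d, visit), sum, 1)

  patient_log <- data.table::data.table(
    patient_id = patient_id,
    visit_start = base_time + 60 * (visit - 1) * arrival_interval,
    visit_end = base_time + 60 * ((visit - 1) * arrival_interval +
                                    visit_len[visit]),
    move_start = base_time + 60 * s_min,
    move_end = base_time + 60 * e_min,
    room_name = room_name,
    room_id = room_id
  )

  ## one resource row per type in the (possibly multiset) step label
  step_types <- strsplit(labels, "+", fixed = TRUE)
  n_ty <- lengths(step_types)
  ridx <- rep(seq_along(labels), n_ty)
  types <- unlist(step_types, use.names = FALSE)
  unit_no <- (visit[ridx] + step[ridx] + seq_along(types)) %% units_per_type + 1
  resource_log <- data.table::data.table(
    resource_id = sprintf("%s_%02d", gsub("[^A-Za-z]", "", types), unit_no),
    resource_type = types,
    room_name = room_name[ridx],
    room_type = "Exam",
    start = base_time + 60 * s_min[ridx],
    end = base_time + 60 * e_min[ridx]
  )

  list(patient_log = patient_log, resource_log = resource_log,
       path_ids = vapply(profiles[pick], `[[`, integer(1), "path_id"))
}

#' Write RTLS logs to delimited files
#'
#' Serializes the output of [generate_synthetic_rtls()] (or any pair of
#' tables in the RTLS schemas) as comma-separated files with ISO-8601
#' timestamps, the format accepted by [parse_rtls_logs()].
#'
#' @param logs list with `patient_log` and `resource_log`.
#' @param patient_path,resource_path output file paths.
#' @return invisibly, a character vector of the two paths.
#' @export
write_rtls_logs <- function(logs, patient_path, resource_path) {
  fmt <- function(dt, ts_cols) {
    out <- data.table::copy(data.table::as.data.table(dt))
    for (cc in ts_cols)
      data.table::set(out, j = cc,
                      value = format(out[[cc]], "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
    out
  }
  data.table::fwrite(fmt(logs$patient_log, .patient_ts), patient_path)
  data.table::fwrite(fmt(logs$resource_log, .resource_ts), resource_path)
  invisible(c(patient_path, resource_path))
}
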