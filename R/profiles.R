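#' Construct a set of pathway profiles
#'
#' A pathway profile describes one dominant care pathway: the ordered
#' resource-type labels of its activities, its occurrence proportion in the
#' patient population, and the per-activity duration moments (minutes and
#' minutes squared) of the fitted log-normal service-time models.
#'
#' An activity step that needs several units of a type at once is written as a
#' multiset label with `+`, e.g. `"Provider+Provider"` for two providers.
#'
#' @param activity_sequences list of character vectors, one per pathway;
#'   element `s` of a vector is the resource-type (multiset) label of step `s`.
#' @param proportions numeric vector of occurrence proportions; must sum to 1
#'   (within 1e-9).
#' @param duration_means list of numeric vectors (minutes), aligned with
#'   `activity_sequences`.
#' @param duration_variances list of numeric vectors (minutes^2), aligned
#'   with `activity_sequences`.
#' @param path_ids optional integer ids; defaults to `0:(n-1)`.
#' @return an object of class `careflow_profiles`: a list of profiles, each a
#'   list with fields `path_id`, `activity_sequence`, `proportion`,
#'   `duration_mean`, `duration_variance`.
#' @export
#' @examples
#' pathway_profiles(
#'   activity_sequences = list(c("Intake", "Provider")),
#'   proportions = 1,
#'   duration_means = list(c(5, 10)),
#'   duration_variances = list(c(2, 30))
#' )
pathway_profiles <- function(activity_sequences, proportions, duration_means,
                             duration_variances, path_ids = NULL) {
  n <- length(activity_sequences)
  if (n == 0) stop_cf("at least one pathway profile is required")
  if (length(proportions) != n || length(duration_means) != n ||
      length(duration_variances) != n)
    stop_cf("profile fields have inconsistent lengths")
  if (is.null(path_ids)) path_ids <- seq_len(n) - 1L
  if (abs(sum(proportions) - 1) > 1e-9)
    stop_cf("pathway proportions must sum to 1 (got %.12g)", sum(proportions))
  profs <- vector("list", n)
  for (i in seq_len(n)) {
    seqv <- as.character(activity_sequences[[i]])
    m <- as.numeric(duration_means[[i]])
    v <- as.numeric(duration_variances[[i]])
    if (length(seqv) < 1) stop_cf("pathway %s has an empty activity sequence",
                                  path_ids[i])
    if (length(m) != length(seqv) || length(v) != length(seqv))
      stop_cf("pathway %s: duration moments do not match sequence length",
              path_ids[i])
    if (any(m <= 0)) stop_cf("pathway %s: duration means must be positive",
                             path_ids[i])
    if (any(v < 0)) stop_cf("pathway %s: duration variances must be >= 0",
                            path_ids[i])
    if (proportions[i] < 0 || proportions[i] > 1)
      stop_cf("pathway %s: proportion outside [0, 1]", path_ids[i])
    profs[[i]] <- list(
      path_id = as.integer(path_ids[i]),
      activity_sequence = seqv,
      proportion = as.numeric(proportions[i]),
      duration_mean = m,
      duration_variance = v
    )
  }
  structure(profs, class = "careflow_profiles")
}

#' Dominant pathway profiles of an outpatient orthopedics clinic
#'
#' The five dominant care pathways mined from three months of RTLS co-location
#' logs of an orthopedics clinic, with their occurrence proportions (used as
#' pathway sampling weights, renormalized over the five retained pathways) and
#' the moments of the fitted log-normal activity-duration distributions.
#' These profiles are the default inputs of the synthetic-data generator and
#' the experiment driver.
#'
#' @return a `careflow_profiles` object with five pathways over the resource
#'   types Intake, Radiology Tech, Provider, Ortho Tech, Discharge.
#' @export
#' @examples
#' as.data.frame(ortho_pathway_profiles())
ortho_pathway_profiles <- function() {
  pathway_profiles(
    activity_sequences = list(
      c("Intake", "Radiology Tech", "Provider", "Ortho Tech", "Discharge"),
      c("Intake", "Provider", "Ortho Tech", "Discharge"),
      c("Intake", "Ortho Tech", "Discharge"),
      c("Intake", "Radiology Tech", "Ortho Tech", "Discharge"),
      c("Intake", "Radiology Tech", "Provider", "Discharge")
    ),
    proportions = c(0.3803, 0.2455, 0.1393, 0.1378, 0.0971) /
      sum(c(0.3803, 0.2455, 0.1393, 0.1378, 0.0971)),
    duration_means = list(
      c(4.7, 3.48, 4.52, 11.62, 3.43),
      c(4.93, 4.99, 12.47, 3.69),
      c(4.75, 11.82, 3.44),
      c(4.91, 3.58, 11.25, 3.49),
      c(5.06, 3.52, 6.15, 3.62)
    ),
    duration_variances = list(
      c(3.25, 4.85, 13.9, 185.52, 2.63),
      c(4.0, 20.11, 206.96, 2.92),
      c(4.35, 232.7, 3.36),
      c(3.75, 5.79, 224.31, 3.31),
      c(3.98, 4.95, 30.61, 4.06)
    ),
    path_ids = 0:4
  )
}

#' @export
print.careflow_profiles <- function(x, ...) {
  cat(sprintf("careflow pathway profiles: %d pathways\n", length(x)))
  for (p in x) {
    cat(sprintf("  path %d (%.2f%%): [%s]\n", p$path_id, 100 * p$proportion,
                paste(p$activity_sequence, collapse = ", ")))
  }
  invisible(x)
}

#' @export
as.data.frame.careflow_profiles <- function(x, ...) {
  data.frame(
    path_id = vapply(x, `[[`, integer(1), "path_id"),
    activity_list = vapply(x, function(p)
      paste(p$activity_sequence, collapse = " | "), character(1)),
    proportion = vapply(x, `[[`, numeric(1), "proportion"),
    n_activities = vapply(x, function(p)
      length(p$activity_sequence), integer(1)),
    duration_means = vapply(x, function(p)
      paste(format(p$duration_mean, trim = TRUE), collapse = " | "),
      character(1)),
    duration_variances = vapply(x, function(p)
      paste(format(p$duration_variance, trim = TRUE), collapse = " | "),
      character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write / read pathway profiles
#'
#' `write_profiles()` stores a `careflow_profiles` object as JSON (the
#' machine-readable profile format) and, alongside it, a human-readable
#' delimited table with the same columns as the dominant-pathway table
#' (path id, activity list, proportion, means, variances) when `table_path`
#' is given. `read_profiles()` reads the JSON form back.
#'
#' @param profiles a `careflow_profiles` object.
#' @param path output (input) JSON file path.
#' @param table_path optional path for a companion CSV table.
#' @return `read_profiles()` returns a `careflow_profiles` object;
#'   `write_profiles()` returns `path` invisibly.
#' @export
write_profiles <- function(profiles, path, table_path = NULL) {
  stopifnot(inherits(profiles, "careflow_profiles"))
  payload <- lapply(profiles, function(p) list(
    path_id = p$path_id,
    activity_sequence = as.list(p$activity_sequence),
    proportion = p$proportion,
    duration_mean = as.list(p$duration_mean),
    duration_variance = as.list(p$duration_variance)
  ))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(table_path))
    utils::write.csv(as.data.frame(profiles), table_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop_cf("profile file not found: %s", path)
  raw <- jsonlite::read_json(path)
  pathway_profiles(
    activity_sequences = lapply(raw, function(p)
      unlist(p$activity_sequence, use.names = FALSE)),
    proportions = vapply(raw, function(p) as.numeric(p$proportion), 1),
    duration_means = lapply(raw, function(p)
      as.numeric(unlist(p$duration_mean))),
    duration_variances = lapply(raw, function(p)
      as.numeric(unlist(p$duration_variance))),
    path_ids = vapply(raw, function(p) as.integer(p$path_id), 1L)
  )
}
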