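#' Serialize and restore problem instances, scenarios and first stages
#'
#' JSON round-tripping used by the command-line interface so that each
#' pipeline stage can run as a separate process. `write_instance()` /
#' `read_instance()` handle `careflow_instance` objects,
#' `write_first_stage()` / `read_first_stage()` the binary first-stage
#' decisions, and `write_scenarios()` / `read_scenarios()` duration
#' scenario matrices (CSV, one row per scenario).
#'
#' @param instance a `careflow_instance`.
#' @param path file path.
#' @return readers return the restored object; writers return `path`
#'   invisibly.
#' @name careflow-io
NULL

#' @rdname careflow-io
#' @export
write_instance <- function(instance, path) {
  stopifnot(inherits(instance, "careflow_instance"))
  payload <- list(
    activities = instance$activities,
    pool = as.list(instance$pool),
    V = list(data = as.vector(instance$V), types = colnames(instance$V)),
    horizon = instance$horizon)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname careflow-io
#' @export
read_instance <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  acts <- data.table::as.data.table(raw$activities)
  acts[, act_id := as.integer(act_id)]
  acts[, pre := as.integer(pre)]
  pool <- resource_pool(raw$pool$type, raw$pool$capacity, raw$pool$unit_id)
  V <- matrix(as.integer(raw$V$data), nrow = nrow(acts),
              dimnames = list(NULL, raw$V$types))
  structure(list(activities = acts, pool = pool, V = V,
                 horizon = as.numeric(raw$horizon)),
            class = "careflow_instance")
}

#' @rdname careflow-io
#' @param first_stage a `careflow_first_stage`.
#' @export
write_first_stage <- function(first_stage, path) {
  stopifnot(inherits(first_stage, "careflow_first_stage"))
  jsonlite::write_json(lapply(unclass(first_stage), as.list), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname careflow-io
#' @export
read_first_stage <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    assignment = data.table::as.data.table(raw$assignment)[
      , .(act_id = as.integer(act_id), unit_id = as.character(unit_id))],
    pairs = data.table::as.data.table(raw$pairs)[
      , .(a = as.integer(a), a2 = as.integer(a2),
          s1 = as.integer(s1), s2 = as.integer(s2))],
    q = data.table::as.data.table(raw$q)[
      , .(a = as.integer(a), a2 = as.integer(a2),
          unit_id = as.character(unit_id), q = as.integer(q))]
  ), class = "careflow_first_stage")
}

#' @rdname careflow-io
#' @param scenarios a `careflow_scenarios` matrix.
#' @export
write_scenarios <- function(scenarios, path) {
  data.table::fwrite(data.table::as.data.table(unclass(scenarios)), path)
  invisible(path)
}

#' @rdname careflow-io
#' @export
read_scenarios <- function(path) {
  m <- as.matrix(data.table::fread(path))
  dimnames(m) <- NULL
  structure(m, class = "careflow_scenarios")
}
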