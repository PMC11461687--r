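#' Tabulate a solved schedule
#'
#' Flattens one scenario's realization of a solution into a delimited-ready
#' table: one row per activity with its patient, pathway position, assigned
#' unit(s), start, duration and wait.
#'
#' @param instance a `careflow_instance`.
#' @param solution a `careflow_solution` (or a list with `first_stage` and
#'   `realizations` in the same shape).
#' @param scenarios the scenario matrix the solution was computed on (used
#'   for durations).
#' @param scenario scenario index (default 1).
#' @return a data.table with columns `scenario`, `act_id`, `patient_id`,
#'   `path_id`, `position`, `resource_types`, `units`, `start`, `duration`,
#'   `end`, `wait`.
#' @export
schedule_table <- function(instance, solution, scenarios, scenario = 1) {
  acts <- instance$activities
  D <- as_scenario_matrix(scenarios, nrow(acts))
  r <- solution$realizations[[scenario]]
  asg <- data.table::as.data.table(solution$first_stage$assignment)
  units <- asg[, .(units = paste(sort(unit_id), collapse = "+")), by = act_id]
  out <- data.table::data.table(
    scenario = scenario,
    act_id = acts$act_id,
    patient_id = acts$patient_id,
    path_id = acts$path_id,
    position = acts$position,
    resource_types = acts$types,
    start = r$b,
    duration = D[scenario, ],
    wait = r$waits)
  out[, end := start + duration]
  merge(out, units, by = "act_id", all.x = TRUE)[order(start, patient_id)]
}

#' Write schedule and Gantt exports
#'
#' `write_schedule()` writes the activity-level table from
#' [schedule_table()]; `write_gantt()` writes a resource-oriented variant
#' (one row per unit per served activity, sorted by unit then start) suitable
#' for drawing a resource-assignment Gantt chart.
#'
#' @inheritParams schedule_table
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(instance, solution, scenarios, path, scenario = 1) {
  data.table::fwrite(schedule_table(instance, solution, scenarios, scenario),
                     path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
write_gantt <- function(instance, solution, scenarios, path, scenario = 1) {
  tab <- schedule_table(instance, solution, scenarios, scenario)
  asg <- data.table::as.data.table(solution$first_stage$assignment)
  g <- merge(asg, tab[, .(act_id, patient_id, resource_types, start, end)],
             by = "act_id")
  data.table::setorder(g, unit_id, start)
  data.table::setcolorder(g, c("unit_id", "act_id", "patient_id",
                               "resource_types", "start", "end"))
  data.table::fwrite(g, path)
  invisible(path)
}
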