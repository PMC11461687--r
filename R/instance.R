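#' Define the clinic resource pool
#'
#' A pool is a table of resource units grouped into types. Each unit `j` has
#' an integer capacity `k_j`: the number of activities it can serve
#' simultaneously (a clinician covering several rooms, a bay with several
#' chairs). Unit ids must be unique across types.
#'
#' @param types character vector of type labels, one entry per unit.
#' @param capacities integer vector of per-unit capacities `k_j >= 1`.
#' @param unit_ids optional unit identifiers; defaults to `<type>_<i>`.
#' @return an object of class `careflow_pool`: a data.table with columns
#'   `unit_id`, `type`, `capacity`.
#' @export
#' @examples
#' resource_pool(c("Provider", "Provider", "Ortho Tech"), c(1, 1, 2))
resource_pool <- function(types, capacities, unit_ids = NULL) {
  n <- length(types)
  if (n == 0) stop_cf("resource pool cannot be empty")
  if (length(capacities) != n)
    stop_cf("types and capacities must have equal length")
  if (any(capacities < 1) || any(capacities != as.integer(capacities)))
    stop_cf("unit capacities must be integers >= 1")
  if (is.null(unit_ids)) {
    unit_ids <- stats::setNames(ave(seq_len(n), types, FUN = seq_along), NULL)
    unit_ids <- sprintf("%s_%d", gsub("[^A-Za-z]", "", types), unit_ids)
  }
  if (anyDuplicated(unit_ids)) stop_cf("unit ids must be unique")
  structure(
    data.table::data.table(unit_id = as.character(unit_ids),
                           type = as.character(types),
                           capacity = as.integer(capacities)),
    class = c("careflow_pool", "data.table", "data.frame"))
}

#' Default resource pool for the orthopedics-clinic pathways
#'
#' Intake and Discharge are not bottleneck steps: they get a single unit with
#' capacity equal to the cohort size so they never bind. The capacitated
#' types are Radiology Tech, Provider and Ortho Tech.
#'
#' @param n_patients cohort size (sets the Intake/Discharge capacity).
#' @param radiology,provider,ortho number of units of each capacitated type.
#' @param capacity per-unit capacity of the capacitated types (default 1).
#' @return a `careflow_pool`.
#' @export
default_ortho_pool <- function(n_patients, radiology = 1, provider = 1,
                               ortho = 1, capacity = 1) {
  resource_pool(
    types = c("Intake", "Discharge",
              rep("Radiology Tech", radiology),
              rep("Provider", provider),
              rep("Ortho Tech", ortho)),
    capacities = c(n_patients, n_patients,
                   rep(capacity, radiology + provider + ortho))
  )
}

#' Sample a patient cohort from pathway profiles
#'
#' Patient `i` (0-based) is scheduled at `t = i * arrival_interval` minutes
#' from the start of the session; the pathway of each patient is drawn from
#' the profile proportions (the pathway sampling weights).
#'
#' @param profiles a `careflow_profiles` object.
#' @param n_patients cohort size (>= 1).
#' @param arrival_interval minutes between consecutive scheduled arrivals.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a data.table with columns `patient_id`, `path_id`,
#'   `scheduled_time` (integer minutes).
#' @export
sample_cohort <- function(profiles, n_patients, arrival_interval = 10,
                          seed = 1L) {
  stopifnot(inherits(profiles, "careflow_profiles"))
  if (!is_count(n_patients) || n_patients < 1)
    stop_cf("n_patients must be a positive integer")
  if (!is_count(arrival_interval) || arrival_interval < 1)
    stop_cf("arrival_interval must be a positive integer")
  props <- vapply(profiles, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-9)
    stop_cf("profile proportions must sum to 1 (got %.12g)", sum(props))
  pick <- with_seed(seed,
    sample.int(length(profiles), n_patients, replace = TRUE, prob = props))
  data.table::data.table(
    patient_id = sprintf("P%03d", seq_len(n_patients) - 1L),
    path_id = vapply(profiles[pick], `[[`, integer(1), "path_id"),
    scheduled_time = as.integer((seq_len(n_patients) - 1L) * arrival_interval)
  )
}

#' Build a scheduling problem instance
#'
#' Expands a cohort into the activity-level optimization instance: one
#' activity per (patient, pathway step), chained by the precedence map
#' `pre(a)`; the requirement matrix `V` counts how many units of each type an
#' activity needs (a multiset step label such as `"Provider+Provider"` needs
#' two). Scheduled times `t_a` apply to initial activities only. Requirements
#' are validated against the pool (`V[a, g] <= |J_g|`).
#'
#' @param cohort data.table from [sample_cohort()] (columns `patient_id`,
#'   `path_id`, `scheduled_time`).
#' @param profiles a `careflow_profiles` object covering the cohort's paths.
#' @param pool a `careflow_pool`.
#' @param horizon session length in minutes (reporting metadata; the model
#'   assumes resources suffice to serve the cohort, so no hard end-of-day
#'   constraint is imposed).
#' @return an object of class `careflow_instance`: a list with
#'   `activities` (data.table: `act_id`, `patient_id`, `path_id`, `position`,
#'   `types` (multiset label), `is_initial`, `scheduled_time`, `pre`,
#'   `duration_mean`, `duration_variance`), `pool`, `V` (activity x type
#'   requirement matrix) and `horizon`.
#' @export
build_instance <- function(cohort, profiles, pool, horizon = 240) {
  stopifnot(inherits(profiles, "careflow_profiles"),
            inherits(pool, "careflow_pool"))
  cohort <- data.table::as.data.table(cohort)
  need <- c("patient_id", "path_id", "scheduled_time")
  if (!all(need %in% names(cohort)))
    stop_cf("cohort must have columns %s", paste(need, collapse = ", "))
  prof_ids <- vapply(profiles, `[[`, integer(1), "path_id")

  rows <- list()
  aid <- 0L
  for (i in seq_len(nrow(cohort))) {
    pidx <- match(cohort$path_id[i], prof_ids)
    if (is.na(pidx))
      stop_cf("cohort patient %s references unknown path_id %s",
              cohort$patient_id[i], cohort$path_id[i])
    p <- profiles[[pidx]]
    L <- length(p$activity_sequence)
    rows[[i]] <- data.table::data.table(
      act_id = aid + seq_len(L),
      patient_id = cohort$patient_id[i],
      path_id = p$path_id,
      position = seq_len(L) - 1L,
      types = p$activity_sequence,
      is_initial = seq_len(L) == 1L,
      scheduled_time = ifelse(seq_len(L) == 1L,
                              as.numeric(cohort$scheduled_time[i]), NA_real_),
      pre = c(NA_integer_, aid + seq_len(L - 1L)),
      duration_mean = p$duration_mean,
      duration_variance = p$duration_variance
    )
    aid <- aid + L
  }
  acts <- data.table::rbindlist(rows)

  type_levels <- sort(unique(pool$type))
  V <- matrix(0L, nrow = nrow(acts), ncol = length(type_levels),
              dimnames = list(NULL, type_levels))
  for (a in seq_len(nrow(acts))) {
    tys <- split_multiset(acts$types[a])
    unknown <- setdiff(tys, type_levels)
    if (length(unknown))
      stop_cf("pathway %s requires resource type '%s' absent from the pool",
              acts$path_id[a], unknown[1])
    tab <- table(tys)
    V[a, names(tab)] <- as.integer(tab)
  }
  pool_n <- table(pool$type)
  for (g in type_levels) {
    too_big <- which(V[, g] > pool_n[[g]])
    if (length(too_big))
      stop_cf(
        "activity %d (patient %s, path %s) needs %d unit(s) of '%s' but the pool has %d",
        too_big[1], acts$patient_id[too_big[1]], acts$path_id[too_big[1]],
        V[too_big[1], g], g, pool_n[[g]])
  }

  structure(
    list(activities = acts, pool = pool, V = V, horizon = as.numeric(horizon)),
    class = "careflow_instance")
}

#' @export
print.careflow_instance <- function(x, ...) {
  a <- x$activities
  cat(sprintf(
    "careflow instance: %d patients, %d activities (%d initial), %d resource units, horizon %g min\n",
    length(unique(a$patient_id)), nrow(a), sum(a$is_initial), nrow(x$pool),
    x$horizon))
  cat("  units:", paste(sprintf("%s[k=%d]", x$pool$unit_id, x$pool$capacity),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Sample integer duration scenarios
#'
#' Draws `N` independent scenarios of activity durations. Each activity's
#' duration is drawn from its moment-fitted log-normal distribution,
#' independently across activities and scenarios, then rounded to the
#' nearest integer minute and clamped to at least 1.
#'
#' @param instance a `careflow_instance`.
#' @param N number of scenarios (>= 1).
#' @param seed integer seed; draws are reproducible given the seed.
#' @return an `N x |A|` integer matrix of class `careflow_scenarios`
#'   (rows = scenarios, columns = activities in `act_id` order), with the
#'   seed stored in attribute `seed`.
#' @export
sample_scenarios <- function(instance, N, seed = 1L) {
  stopifnot(inherits(instance, "careflow_instance"))
  if (!is_count(N) || N < 1) stop_cf("N must be a positive integer")
  acts <- instance$activities
  D <- with_seed(seed, {
    m <- matrix(0L, nrow = N, ncol = nrow(acts))
    for (a in seq_len(nrow(acts))) {
      par <- lognormal_from_moments(acts$duration_mean[a],
                                    acts$duration_variance[a])
      m[, a] <- as.integer(pmax(1, round(sample_lognormal(N, par))))
    }
    m
  })
  structure(D, class = "careflow_scenarios", seed = as.integer(seed))
}

#' Mean-value duration scenario
#'
#' The single scenario used by the deterministic baseline: each activity's
#' duration is its profile mean rounded to the nearest integer minute and
#' clamped to at least 1.
#'
#' @param instance a `careflow_instance`.
#' @return a `1 x |A|` integer matrix of class `careflow_scenarios`, tagged
#'   with attribute `mean_value = TRUE`.
#' @export
mean_value_durations <- function(instance) {
  stopifnot(inherits(instance, "careflow_instance"))
  d <- as.integer(pmax(1, round(instance$activities$duration_mean)))
  structure(matrix(d, nrow = 1), class = "careflow_scenarios",
            mean_value = TRUE)
}
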