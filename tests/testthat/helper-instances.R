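## Shared fixture builders. Everything is generated in code; no stored data.

## Single-pathway profile over arbitrary type labels.
toy_profile <- function(types, means = NULL, vars = NULL, path_id = 0L) {
  L <- length(types)
  pathway_profiles(
    activity_sequences = list(types),
    proportions = 1,
    duration_means = list(means %||% rep(5, L)),
    duration_variances = list(vars %||% rep(0, L)),
    path_ids = path_id)
}

## The worked 2-patient contention example: both arrive at t = 0 on
## [Intake, Provider], two Intake units, one capacity-1 Provider,
## deterministic durations (2, 5); one Provider visit must wait 5 minutes.
provider_example <- function() {
  prof <- toy_profile(c("Intake", "Provider"), means = c(2, 5))
  cohort <- data.table::data.table(patient_id = c("P0", "P1"), path_id = 0L,
                                   scheduled_time = c(0, 0))
  pool <- resource_pool(c("Intake", "Intake", "Provider"), c(1, 1, 1))
  build_instance(cohort, prof, pool)
}

## Random tiny instance for oracle cross-validation: 2-3 patients, chain
## length <= 3, <= 2 units per type, unit capacities in {1, 2}, staggered
## or simultaneous arrivals. Deterministic given seed.
random_tiny_instance <- function(seed) {
  with_seed <- get("with_seed", asNamespace("careflow"))
  with_seed(seed, {
    npat <- sample(2:3, 1)
    L <- sample(2:3, 1)
    types <- LETTERS[seq_len(L)]
    prof <- toy_profile(types, means = runif(L, 2, 8),
                        vars = runif(L, 0, 30))
    n_units <- sample(1:2, L, replace = TRUE)
    pool <- resource_pool(rep(types, n_units),
                          sample(1:2, sum(n_units), replace = TRUE))
    gap <- sample(c(0, 3, 5, 10), 1)
    cohort <- data.table::data.table(
      patient_id = sprintf("P%d", seq_len(npat)), path_id = 0L,
      scheduled_time = (seq_len(npat) - 1) * gap)
    build_instance(cohort, prof, pool)
  })
}

## Default-pool instance sampled from the clinic pathway table.
ortho_instance <- function(n_patients, interval, seed,
                           radiology = 1, provider = 1, ortho = 1) {
  prof <- ortho_pathway_profiles()
  cohort <- sample_cohort(prof, n_patients, interval, seed = seed)
  build_instance(cohort, prof,
                 default_ortho_pool(n_patients, radiology, provider, ortho))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
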