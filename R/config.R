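## Configuration schema: section -> field -> c(default, min, max). All
## numeric; units are minutes (times), counts, fractions or seconds as noted.
.config_schema <- list(
  run = list(
    n_patients = c(4, 1, Inf),          # cohort size
    arrival_interval = c(10, 1, Inf),   # minutes between arrivals
    horizon = c(240, 1, Inf),           # session length, minutes
    top_k = c(5, 1, Inf),               # pathways retained by mining
    seed = c(1, 0, Inf)
  ),
  pool = list(
    radiology = c(1, 0, Inf),           # units of Radiology Tech
    provider = c(1, 0, Inf),            # units of Provider
    ortho = c(1, 0, Inf),               # units of Ortho Tech
    capacity = c(1, 1, Inf)             # per-unit capacity of those types
  ),
  mco = list(
    N0 = c(100, 1, Inf),
    n_prime = c(500, 1, Inf),
    K = c(10, 1, Inf),
    epsilon = c(0.05, 1e-12, 1 - 1e-12),
    growth = c(2, 1 + 1e-9, Inf),
    max_iter = c(5, 1, Inf)
  ),
  solver = list(
    mip_gap = c(1e-4, 0, 1),
    time_limit = c(3600, 1, Inf)        # seconds per model
  )
)

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with sections `run`, `pool`, `mco` and
#' `solver`; every field has a documented default (notably `N0 = 100`,
#' `n_prime = 500`, `K = 10`, `epsilon = 0.05`, `mip_gap = 1e-4`,
#' `time_limit = 3600` s), so an empty file yields pure defaults. Unknown
#' sections or keys are rejected (typo safety) and range violations are
#' named. The resolved configuration is tagged `desk_scale` when the
#' implied first-stage model is small enough for interactive solving with
#' an open-source backend (activity-pair count below 2500, roughly 10
#' patients).
#'
#' @param path path to a YAML file; missing file is an error, an empty file
#'   yields defaults.
#' @return a validated nested list of class `careflow_config`, with
#'   `desk_scale` attribute.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_cf("configuration file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(.config_schema))
  if (length(unknown))
    stop_cf("unknown configuration section '%s' (known: %s)", unknown[1],
            paste(names(.config_schema), collapse = ", "))
  out <- list()
  for (sec in names(.config_schema)) {
    schema <- .config_schema[[sec]]
    given <- raw[[sec]] %||% list()
    unknown <- setdiff(names(given), names(schema))
    if (length(unknown))
      stop_cf("unknown key '%s' in section '%s' (known: %s)", unknown[1], sec,
              paste(names(schema), collapse = ", "))
    vals <- list()
    for (key in names(schema)) {
      v <- given[[key]] %||% schema[[key]][1]
      if (!is.numeric(v) || length(v) != 1 || is.na(v))
        stop_cf("configuration %s.%s must be a single number", sec, key)
      if (v < schema[[key]][2] || v > schema[[key]][3])
        stop_cf("configuration %s.%s = %g outside allowed range [%g, %g]",
                sec, key, v, schema[[key]][2], schema[[key]][3])
      vals[[key]] <- v
    }
    out[[sec]] <- vals
  }
  if (out$mco$n_prime < out$mco$N0)
    stop_cf("configuration mco.n_prime must be >= mco.N0")
  ## rough first-stage size: activity pairs grow quadratically in patients
  est_acts <- out$run$n_patients * 4.3
  attr(out, "desk_scale") <- est_acts^2 < 2500
  class(out) <- "careflow_config"
  out
}
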