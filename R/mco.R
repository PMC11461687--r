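#' Monte Carlo optimization configuration
#'
#' Controls the iterative sample-size search: starting from a small SAA
#' sample size `N0`, each iteration runs `K` independent replicates of
#' optimize-then-simulate, compares the replicate-averaged optimization
#' value (statistical lower bound) with the replicate-averaged simulation
#' value on `n_prime` fresh scenarios (statistical upper bound), and stops
#' when the approximate optimality index falls below `epsilon`; otherwise
#' `N` is grown geometrically.
#'
#' @param N0 initial SAA sample size (default 100).
#' @param n_prime simulation sample size `N'` (default 500; must be
#'   at least `N0`).
#' @param K replicates per iteration (default 10).
#' @param epsilon AOI stopping tolerance in (0, 1) (default 0.05).
#' @param growth geometric growth factor for `N` between iterations
#'   (default 2).
#' @param max_iter maximum iterations before flagging non-convergence
#'   (default 5).
#' @param seed master seed; all replicate scenario draws derive from it via
#'   [child_seed()].
#' @return an object of class `careflow_mco_config`.
#' @export
mco_config <- function(N0 = 100, n_prime = 500, K = 10, epsilon = 0.05,
                       growth = 2, max_iter = 5, seed = 1L) {
  if (!is_count(N0) || N0 < 1) stop_cf("N0 must be a positive integer")
  if (!is_count(n_prime) || n_prime < N0)
    stop_cf("n_prime must be an integer >= N0 (the optimization sample is far smaller than the simulation sample)")
  if (!is_count(K) || K < 1) stop_cf("K must be a positive integer")
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 1)
    stop_cf("epsilon must lie in (0, 1)")
  if (!is.numeric(growth) || growth <= 1) stop_cf("growth must exceed 1")
  if (!is_count(max_iter) || max_iter < 1)
    stop_cf("max_iter must be a positive integer")
  structure(list(N0 = as.integer(N0), n_prime = as.integer(n_prime),
                 K = as.integer(K), epsilon = epsilon, growth = growth,
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "careflow_mco_config")
}

#' Approximate optimality index
#'
#' The relative gap between the statistical upper bound (average simulation
#' objective on fresh scenarios) and the statistical lower bound (average
#' SAA optimum): \eqn{AOI = |\bar v_{N'} - \bar v_N| / \bar v_{N'}}.
#' Defined as 0 when both bounds are 0 (a cohort with no waiting at all);
#' undefined when only the upper bound is 0.
#'
#' @param v_bar_N average optimization objective over replicates (minutes).
#' @param v_bar_n_prime average simulation objective over replicates
#'   (minutes); must be non-negative.
#' @return the AOI as a fraction.
#' @export
#' @examples
#' compute_aoi(96, 100) # 0.04
compute_aoi <- function(v_bar_N, v_bar_n_prime) {
  if (v_bar_n_prime < 0) stop_cf("the simulation bound must be non-negative")
  if (v_bar_n_prime == 0) {
    if (abs(v_bar_N) < 1e-12) return(0)
    stop_cf("AOI undefined: simulation bound is 0 but optimization bound is %g",
            v_bar_N)
  }
  abs(v_bar_n_prime - v_bar_N) / v_bar_n_prime
}

#' Run the Monte Carlo optimization procedure
#'
#' For each iteration and each of `K` replicates, `N + N'` i.i.d. duration
#' scenarios are drawn; the SAA model is solved on the first `N` (yielding
#' the replicate optimization value and a first-stage solution) and that
#' fixed first stage is evaluated on the remaining `N'` (the replicate
#' simulation value). Replicate averages give the statistical lower and
#' upper bounds of the two-stage optimum and the AOI; the loop stops when
#' AOI drops below the tolerance, otherwise `N` grows.
#'
#' The retained first-stage solution is the final iteration's best replicate
#' by simulation value; the final iteration's simulation scenario sets are
#' kept for a common-scenario VSS comparison ([compute_vss()]).
#'
#' @param instance a `careflow_instance`.
#' @param cfg an [mco_config()].
#' @param solver_cfg a [solver_config()].
#' @return an object of class `careflow_mco`: list with `iterations` (each:
#'   `N`, replicate values `v_k_N` and `v_k_n_prime`, means, standard
#'   errors, `aoi`, wall-clock seconds), `converged`, `first_stage`,
#'   `v_bar_N`, `v_bar_n_prime`, `aoi`, `sim_scenarios` (list of `K`
#'   scenario matrices), `config`.
#' @export
run_mco <- function(instance, cfg = mco_config(), solver_cfg = solver_config()) {
  stopifnot(inherits(instance, "careflow_instance"),
            inherits(cfg, "careflow_mco_config"))
  nA <- nrow(instance$activities)
  N <- cfg$N0
  iterations <- list()
  converged <- FALSE
  fs_final <- NULL
  sims_final <- NULL

  for (it in seq_len(cfg$max_iter)) {
    v_k_N <- v_k_np <- numeric(cfg$K)
    fss <- vector("list", cfg$K)
    sims <- vector("list", cfg$K)
    t0 <- proc.time()[["elapsed"]]
    opt_time <- 0
    for (k in seq_len(cfg$K)) {
      scen <- sample_scenarios(instance, N + cfg$n_prime,
                               seed = child_seed(cfg$seed, it, k))
      sol <- solve_saa(instance, scen[seq_len(N), , drop = FALSE], solver_cfg)
      opt_time <- opt_time + sol$solve_time
      v_k_N[k] <- sol$v_N
      sims[[k]] <- scen[N + seq_len(cfg$n_prime), , drop = FALSE]
      ev <- evaluate_first_stage(instance, sol$first_stage, sims[[k]],
                                 solver_cfg)
      v_k_np[k] <- ev$v_bar
      fss[[k]] <- sol$first_stage
    }
    v_bar_N <- mean(v_k_N)
    v_bar_np <- mean(v_k_np)
    aoi <- compute_aoi(v_bar_N, v_bar_np)
    iterations[[it]] <- list(
      N = N, v_k_N = v_k_N, v_k_n_prime = v_k_np,
      v_bar_N = v_bar_N, v_bar_n_prime = v_bar_np,
      se_N = if (cfg$K > 1) stats::sd(v_k_N) / sqrt(cfg$K) else 0,
      se_n_prime = if (cfg$K > 1) stats::sd(v_k_np) / sqrt(cfg$K) else 0,
      aoi = aoi, opt_time = opt_time,
      wall_time = proc.time()[["elapsed"]] - t0)
    fs_final <- fss[[which.min(v_k_np)]]
    sims_final <- sims
    if (aoi < cfg$epsilon) { converged <- TRUE; break }
    N <- as.integer(ceiling(N * cfg$growth))
  }

  last <- iterations[[length(iterations)]]
  structure(list(iterations = iterations, converged = converged,
                 first_stage = fs_final,
                 v_bar_N = last$v_bar_N, v_bar_n_prime = last$v_bar_n_prime,
                 aoi = last$aoi, N_final = last$N,
                 sim_scenarios = sims_final, config = cfg),
            class = "careflow_mco")
}

#' @export
print.careflow_mco <- function(x, ...) {
  cat(sprintf("careflow MCO: %d iteration(s), %s\n", length(x$iterations),
              if (x$converged) "converged" else "NOT converged"))
  for (it in x$iterations)
    cat(sprintf("  N = %d: v_bar_N = %.3f, v_bar_N' = %.3f, AOI = %.4f\n",
                it$N, it$v_bar_N, it$v_bar_n_prime, it$aoi))
  invisible(x)
}

#' Value of the stochastic solution
#'
#' Quantifies what modelling duration uncertainty buys. The mean-value
#' baseline solves the deterministic model with every duration at its
#' (rounded) mean and fixes that first stage; both the stochastic and the
#' baseline first stages are then evaluated on the same retained simulation
#' scenario sets from the final MCO iteration. The report uses the
#' convention `VSS = v_base - v_stochastic` (positive when the stochastic
#' solution waits less); the ratio `VSS / v_base` is the fractional
#' waiting-time reduction relative to the baseline.
#'
#' @param instance a `careflow_instance`.
#' @param mco a `careflow_mco` result carrying retained simulation
#'   scenarios.
#' @param solver_cfg a [solver_config()].
#' @return an object of class `careflow_vss`: list with `v_base`
#'   (baseline mean, minutes), `v_stochastic` (`v_bar_n_prime`), `vss`,
#'   `ratio`, `se` (standard error of the replicate VSS estimates),
#'   `replicates` (per-replicate baseline and stochastic values), and
#'   `difference_estimator` (`v_stochastic - v_base`).
#' @export
compute_vss <- function(instance, mco, solver_cfg = solver_config()) {
  stopifnot(inherits(mco, "careflow_mco"))
  if (is.null(mco$sim_scenarios) || !length(mco$sim_scenarios))
    stop_cf("MCO result carries no retained simulation scenarios")
  nA <- nrow(instance$activities)
  if (ncol(mco$sim_scenarios[[1]]) != nA)
    stop_cf("retained scenarios do not match the instance (%d vs %d activities)",
            ncol(mco$sim_scenarios[[1]]), nA)
  base_sol <- solve_deterministic(instance, mean_value_durations(instance),
                                  solver_cfg)
  v_base_k <- vapply(mco$sim_scenarios, function(S)
    evaluate_first_stage(instance, base_sol$first_stage, S, solver_cfg)$v_bar,
    1)
  last <- mco$iterations[[length(mco$iterations)]]
  v_sto_k <- last$v_k_n_prime
  vss_k <- v_base_k - v_sto_k
  v_base <- mean(v_base_k)
  vss <- v_base - mco$v_bar_n_prime
  structure(list(
    v_base = v_base,
    v_stochastic = mco$v_bar_n_prime,
    vss = vss,
    ratio = if (v_base > 0) vss / v_base else 0,
    se = if (length(vss_k) > 1) stats::sd(vss_k) / sqrt(length(vss_k)) else 0,
    replicates = data.table::data.table(v_base = v_base_k,
                                        v_stochastic = v_sto_k, vss = vss_k),
    difference_estimator = mco$v_bar_n_prime - v_base
  ), class = "careflow_vss")
}

#' @export
print.careflow_vss <- function(x, ...) {
  cat(sprintf(
    "VSS = %.3f min (baseline %.3f, stochastic %.3f): %.1f%% waiting-time reduction\n",
    x$vss, x$v_base, x$v_stochastic, 100 * x$ratio))
  invisible(x)
}

#' Run an experiment grid
#'
#' Executes the full pipeline (sample cohort, build instance, run MCO,
#' compute VSS) over the cross product of cohort sizes, arrival intervals
#' and capacity configurations, one seeded trial per cell. Per-cell solver
#' failures are recorded in the row and the grid continues.
#'
#' @param profiles a `careflow_profiles` object.
#' @param grid list with `n_patients` (integer vector), `interval` (integer
#'   vector, minutes) and optionally `capacity` (list of lists with fields
#'   `radiology`, `provider`, `ortho`; default one unit of each).
#' @param cfg an [mco_config()] (its `seed` is overridden per cell).
#' @param solver_cfg a [solver_config()].
#' @param seed master seed for the grid.
#' @param horizon session length passed to [build_instance()].
#' @return a data.table with one row per cell: setting columns, `vss`,
#'   `ratio`, `aoi`, `N_final`, `converged`, `opt_time`, `cell_seed`,
#'   `error` (NA on success).
#' @export
run_experiment_grid <- function(profiles, grid, cfg = mco_config(),
                                solver_cfg = solver_config(), seed = 1L,
                                horizon = 240) {
  stopifnot(length(grid$n_patients) >= 1, length(grid$interval) >= 1)
  caps <- grid$capacity %||% list(list(radiology = 1, provider = 1, ortho = 1))
  cells <- expand.grid(np = grid$n_patients, iv = grid$interval,
                       cap = seq_along(caps))
  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    np <- cells$np[ci]; iv <- cells$iv[ci]; cp <- caps[[cells$cap[ci]]]
    cell_seed <- child_seed(seed, ci)
    row <- data.table::data.table(
      n_patients = np, interval = iv,
      radiology = cp$radiology, provider = cp$provider, ortho = cp$ortho,
      vss = NA_real_, ratio = NA_real_, aoi = NA_real_,
      N_final = NA_integer_, converged = NA, opt_time = NA_real_,
      cell_seed = cell_seed, error = NA_character_)
    res <- tryCatch({
      cohort <- sample_cohort(profiles, np, iv, seed = child_seed(cell_seed, 1))
      pool <- default_ortho_pool(np, radiology = cp$radiology,
                                 provider = cp$provider, ortho = cp$ortho)
      inst <- build_instance(cohort, profiles, pool, horizon = horizon)
      mcfg <- cfg
      mcfg$seed <- child_seed(cell_seed, 2)
      mco <- run_mco(inst, mcfg, solver_cfg)
      vss <- compute_vss(inst, mco, solver_cfg)
      row$vss <- vss$vss
      row$ratio <- vss$ratio
      row$aoi <- mco$aoi
      row$N_final <- mco$N_final
      row$converged <- mco$converged
      row$opt_time <- sum(vapply(mco$iterations, `[[`, 1, "opt_time"))
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[ci]] <- res
  }
  data.table::rbindlist(rows)
}
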