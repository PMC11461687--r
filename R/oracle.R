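#' Exact minimum total waiting time by exhaustive search
#'
#' An independent oracle for validating the MILP solver on tiny instances.
#' It performs a depth-first branch-and-bound over discrete schedules: it
#' enumerates precedence-consistent placement orders (activities placed in
#' nondecreasing start time), unit assignments, and for each partial order
#' places the next activity at the earliest integer minute satisfying
#' release, precedence and capacity-at-every-start. Any feasible schedule's
#' start order, replayed greedily, yields pointwise-earlier starts, so the
#' search space contains an optimal schedule; partial waiting-time bounds
#' prune the tree. The formulation shares nothing with the big-M model or
#' its solver backend.
#'
#' Symmetry is reduced by (i) restricting interchangeable so-far-unused
#' units of a type to the lowest-numbered one and (ii) breaking ties between
#' simultaneous starts by activity index.
#'
#' @param instance a `careflow_instance` (intended for at most ~12
#'   activities).
#' @param durations a duration vector or single-row scenario matrix.
#' @param horizon optional integer cap on start times; defaults to the safe
#'   bound `max t_a + sum of durations`. If no schedule fits under a
#'   user-supplied cap, an error reports the minimal feasible bound.
#' @return a list with `objective` (minutes), `b` (start times),
#'   `assignment` (data.table `act_id`, `unit_id`).
#' @export
brute_force_optimum <- function(instance, durations, horizon = NULL) {
  acts <- instance$activities
  pool <- instance$pool
  V <- instance$V
  nA <- nrow(acts)
  if (nA > 14)
    stop_cf("brute_force_optimum is an oracle for tiny instances (<= 14 activities), got %d", nA)
  D <- as_scenario_matrix(durations, nA)
  d <- as.numeric(D[1, ])
  t0 <- ifelse(acts$is_initial, acts$scheduled_time, 0)
  pre <- acts$pre
  safe_cap <- max(t0) + sum(d)
  cap <- if (is.null(horizon)) safe_cap else as.numeric(horizon)

  ## per-activity unit-combination choices (list of integer pool-row vectors)
  combos_of <- lapply(seq_len(nA), function(a) {
    per_type <- lapply(colnames(V)[V[a, ] > 0], function(g) {
      js <- which(pool$type == g)
      ## combn over positions: combn(n, m) would expand a scalar js to 1:n
      lapply(utils::combn(seq_along(js), V[a, g], simplify = FALSE),
             function(ii) js[ii])
    })
    out <- list(integer())
    for (ch in per_type)
      out <- unlist(lapply(out, function(base)
        lapply(ch, function(js) c(base, js))), recursive = FALSE)
    out
  })

  env <- new.env()
  env$best <- Inf
  env$best_b <- NULL
  env$best_units <- NULL
  b <- rep(NA_real_, nA)
  units <- vector("list", nA)
  used <- rep(FALSE, nrow(pool)) # unit ever used (for symmetry pruning)

  feasible_at <- function(tau, js, placed) {
    for (j in js) {
      cov <- 0L
      for (m in placed) if (j %in% units[[m]] &&
                            b[m] <= tau && b[m] + d[m] > tau) cov <- cov + 1L
      if (cov + 1L > pool$capacity[j]) return(FALSE)
    }
    TRUE
  }

  dfs <- function(placed, partial, cur_b, last_act) {
    if (length(placed) == nA) {
      if (partial < env$best) {
        env$best <- partial
        env$best_b <- b
        env$best_units <- units
      }
      return()
    }
    cand <- setdiff(seq_len(nA), placed)
    cand <- cand[is.na(pre[cand]) | pre[cand] %in% placed]
    for (a in cand) {
      ready <- if (is.na(pre[a])) t0[a] else b[pre[a]] + d[pre[a]]
      lbt <- max(ready, cur_b)
      for (js in combos_of[[a]]) {
        ## symmetry: among never-used units of identical (type, capacity),
        ## only the lowest-numbered may be picked
        skip <- FALSE
        for (j in js) {
          if (!used[j]) {
            twins <- which(pool$type == pool$type[j] &
                             pool$capacity == pool$capacity[j] & !used)
            twins <- setdiff(twins, js)
            if (any(twins < j)) { skip <- TRUE; break }
          }
        }
        if (skip) next
        tau <- lbt
        while (tau <= cap && !feasible_at(tau, js, placed)) tau <- tau + 1
        if (tau > cap) next
        if (tau == cur_b && !is.na(last_act) && a < last_act) next # tie order
        w <- tau - ready
        if (partial + w >= env$best) next
        b[a] <<- tau
        units[[a]] <<- js
        prev_used <- used[js]
        used[js] <<- TRUE
        dfs(c(placed, a), partial + w, tau, a)
        used[js] <<- prev_used
        b[a] <<- NA_real_
        units[a] <<- list(integer())
      }
    }
  }
  dfs(integer(), 0, 0, NA_integer_)

  if (!is.finite(env$best)) {
    if (!is.null(horizon) && cap < safe_cap)
      stop_cf("horizon %g too small to fit all activities; %g is always sufficient",
              cap, safe_cap)
    stop_cf("no feasible schedule found (inconsistent instance)")
  }
  asg <- data.table::rbindlist(lapply(seq_len(nA), function(a)
    data.table::data.table(act_id = a, unit_id = pool$unit_id[env$best_units[[a]]])))
  list(objective = env$best, b = env$best_b, assignment = asg)
}
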