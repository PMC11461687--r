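## Earliest schedule consistent with a fixed first stage, for one duration
## vector. With the binaries fixed, the second-stage constraints form a
## system of difference constraints; its least element (all starts as early
## as possible) minimizes the total waiting objective and is computed by a
## longest-path fixpoint. A positive cycle means the fixed sequencing is
## inconsistent with the new durations; that can only involve s2 = 1 pairs,
## whose (2g) "start before a' ends" constraint may clash with precedence
## when durations shrink. Those constraints are dropped per offending pair
## (capacity-safe: starting later than planned only reduces concurrency) and
## the realization is marked relaxed.
schedule_fixed <- function(instance, first_stage, d, relax = TRUE) {
  acts <- instance$activities
  nA <- nrow(acts)
  d <- as.numeric(d)
  pr <- first_stage$pairs

  L <- ifelse(acts$is_initial, acts$scheduled_time, 0)
  a1 <- which(!acts$is_initial)
  eu <- acts$pre[a1]; ev <- a1; ew <- d[acts$pre[a1]]
  ep <- rep(NA_integer_, length(a1))         # pair row for relaxable edges
  if (nrow(pr)) {
    i1 <- pr$s1 == 1L
    eu <- c(eu, pr$a2[i1], pr$a[!i1])
    ev <- c(ev, pr$a[i1], pr$a2[!i1])
    ew <- c(ew, rep(0, sum(i1)), rep(1, sum(!i1)))
    ep <- c(ep, rep(NA_integer_, nrow(pr)))
    i2 <- pr$s2 == 1L
    eu <- c(eu, pr$a2[!i2], pr$a[i2])
    ev <- c(ev, pr$a[!i2], pr$a2[i2])
    ew <- c(ew, d[pr$a2[!i2]], 1 - d[pr$a2[i2]])
    ep <- c(ep, rep(NA_integer_, sum(!i2)), which(i2))
  }

  ## least fixpoint of b[v] >= max(L[v], b[u] + w); NULL on positive cycle
  fixpoint <- function(eu, ev, ew, max_sweeps) {
    b <- L
    for (sweep in seq_len(max_sweeps)) {
      cand <- b[eu] + ew
      imp <- which(cand > b[ev] + 1e-9)
      if (!length(imp)) return(b)
      best <- tapply(cand[imp], ev[imp], max)
      b[as.integer(names(best))] <- as.numeric(best)
    }
    NULL
  }

  relaxed <- integer()
  repeat {
    ## sweeps bound: each sweep finalizes at least one node of the longest
    ## constraint chain, so nA + 1 sweeps suffice unless a cycle is positive
    b <- fixpoint(eu, ev, ew, nA + 1L)
    if (!is.null(b)) {
      waits <- ifelse(acts$is_initial, b - acts$scheduled_time,
                      b - b[acts$pre] - d[acts$pre])
      waits[is.na(waits)] <- 0
      return(list(b = b, waits = waits, objective = sum(waits),
                  relaxed_pairs = relaxed))
    }
    if (!relax)
      stop_cf("fixed first stage infeasible for this duration scenario")
    ## a positive cycle must pass through an s2 = 1 edge (all other
    ## constraints are duration-safe); find the offenders against the least
    ## solution of the system without any s2 = 1 edges and drop them
    hard <- which(is.na(ep))
    b0 <- fixpoint(eu[hard], ev[hard], ew[hard], nA + 1L)
    if (is.null(b0))
      stop_cf("inconsistent fixed sequencing: positive cycle without a relaxable (2g) constraint")
    soft <- which(!is.na(ep))
    viol <- soft[b0[eu[soft]] + ew[soft] > b0[ev[soft]] + 1e-9]
    if (!length(viol))
      stop_cf("internal error: infeasible system with no violated (2g) constraint")
    relaxed <- sort(unique(c(relaxed, ep[viol])))
    keep <- setdiff(seq_along(eu), viol)
    eu <- eu[keep]; ev <- ev[keep]; ew <- ew[keep]; ep <- ep[keep]
  }
}

## Expected ordered pairs (both directions) sharing >= 1 required type.
expected_pairs <- function(instance) {
  req <- instance$V > 0
  share <- tcrossprod(req) > 0
  diag(share) <- FALSE
  idx <- which(share, arr.ind = TRUE)
  data.table::setorder(
    data.table::data.table(a = idx[, 1], a2 = idx[, 2]), a, a2)[]
}

## First-stage invariant checks: assignment counts (1b), pair coverage,
## binary values, concurrency linkage (1c) and capacity (1d).
validate_first_stage <- function(instance, fs) {
  if (!inherits(fs, "careflow_first_stage"))
    stop_cf("first_stage must be a careflow_first_stage object")
  acts <- instance$activities; pool <- instance$pool; V <- instance$V
  asg <- data.table::as.data.table(fs$assignment)
  if (anyDuplicated(asg[, .(act_id, unit_id)]))
    stop_cf("first stage assigns a unit to the same activity twice")
  bad <- setdiff(asg$unit_id, pool$unit_id)
  if (length(bad)) stop_cf("first stage references unknown unit '%s'", bad[1])
  cnt <- asg[, .(n = .N), by = .(act_id, g = pool$type[match(unit_id, pool$unit_id)])]
  full <- data.table::data.table(
    act_id = rep(seq_len(nrow(V)), times = ncol(V)),
    g = rep(colnames(V), each = nrow(V)),
    needed = as.integer(as.vector(V)))
  full <- merge(full, cnt, by = c("act_id", "g"), all.x = TRUE)
  full[is.na(n), n := 0L]
  off <- full[n != needed]
  if (nrow(off))
    stop_cf("assignment count violates requirement: activity %d needs %d unit(s) of '%s', got %d",
            off$act_id[1], off$needed[1], off$g[1], off$n[1])
  ep <- expected_pairs(instance)
  pr <- data.table::as.data.table(fs$pairs)
  if (!all(pr$s1 %in% 0:1) || !all(pr$s2 %in% 0:1))
    stop_cf("sequencing indicators must be binary")
  if (nrow(ep) != nrow(pr) ||
      nrow(merge(ep, pr[, .(a, a2)], by = c("a", "a2"))) != nrow(ep))
    stop_cf("first stage must carry s1/s2 for every ordered pair sharing a required type")
  ## (1c)/(1d) on q
  qd <- data.table::as.data.table(fs$q)
  if (nrow(qd)) {
    key <- merge(qd, pr, by = c("a", "a2"))
    xj <- asg[, .(act_id, unit_id, x = 1L)]
    key <- merge(key, xj, by.x = c("a", "unit_id"),
                 by.y = c("act_id", "unit_id"), all.x = TRUE)
    data.table::setnames(key, "x", "xa")
    key <- merge(key, xj, by.x = c("a2", "unit_id"),
                 by.y = c("act_id", "unit_id"), all.x = TRUE)
    data.table::setnames(key, "x", "xa2")
    key[is.na(xa), xa := 0L]; key[is.na(xa2), xa2 := 0L]
    viol <- key[q < s1 + s2 + xa + xa2 - 3L]
    if (nrow(viol))
      stop_cf("concurrency indicator q[%d,%d,%s] violates its linkage constraint",
              viol$a[1], viol$a2[1], viol$unit_id[1])
    capv <- key[, .(tot = sum(q)), by = .(a, unit_id)]
    capv[, k := pool$capacity[match(unit_id, pool$unit_id)]]
    bad <- capv[tot > k - 1L]
    if (nrow(bad))
      stop_cf("capacity constraint violated for unit %s at activity %d (%d concurrent, capacity %d)",
              bad$unit_id[1], bad$a[1], bad$tot[1] + 1L, bad$k[1])
  }
  invisible(TRUE)
}

#' Evaluate a fixed first-stage solution on duration scenarios
#'
#' With all first-stage binaries fixed, each scenario's second-stage problem
#' is a linear program over start times; its exact optimum (the earliest
#' schedule consistent with the fixed assignment and sequencing) is computed
#' per scenario and averaged. This is the simulation stage of the Monte
#' Carlo optimization loop: the average is a statistical upper bound on the
#' optimal expected waiting time.
#'
#' If a scenario's shrunken durations make an `s2 = 1` "starts before a'
#' ends" constraint inconsistent with precedence, that constraint is dropped
#' for the offending pair(s) only — starting later than planned can only
#' reduce concurrency, so the relaxation is capacity-safe — and the scenario
#' is marked relaxed in the output.
#'
#' @param instance a `careflow_instance`.
#' @param first_stage a `careflow_first_stage` (from a [solve_saa()] /
#'   [solve_deterministic()] solution); its invariants are validated before
#'   solving.
#' @param scenarios a `careflow_scenarios` matrix.
#' @param cfg a [solver_config()] (carried for interface symmetry; the
#'   per-scenario problems are solved exactly in closed form).
#' @return an object of class `careflow_evaluation`: list with
#'   `realizations` (per scenario `b`, `waits`, `objective`,
#'   `relaxed_pairs`), `v_bar` (average objective, minutes),
#'   `relaxed_scenarios` (indices).
#' @export
evaluate_first_stage <- function(instance, first_stage, scenarios,
                                 cfg = solver_config()) {
  stopifnot(inherits(instance, "careflow_instance"))
  validate_first_stage(instance, first_stage)
  D <- as_scenario_matrix(scenarios, nrow(instance$activities))
  realizations <- lapply(seq_len(nrow(D)), function(n)
    schedule_fixed(instance, first_stage, D[n, ], relax = TRUE))
  v_bar <- mean(vapply(realizations, `[[`, 1, "objective"))
  relaxed <- which(vapply(realizations, function(r)
    length(r$relaxed_pairs) > 0, TRUE))
  structure(list(realizations = realizations, v_bar = v_bar,
                 relaxed_scenarios = relaxed),
            class = "careflow_evaluation")
}

#' @export
print.careflow_evaluation <- function(x, ...) {
  cat(sprintf(
    "careflow evaluation: v_bar = %.4g min over %d scenario(s), %d relaxed\n",
    x$v_bar, length(x$realizations), length(x$relaxed_scenarios)))
  invisible(x)
}

#' Independently verify a schedule against the instance constraints
#'
#' A solver-free feasibility audit: trusts only the assignment `x` and the
#' start times `b`, never the sequencing or concurrency indicators. Checks
#' assignment counts against the requirement matrix, release times of
#' initial activities, precedence, and resource capacity. Capacity is
#' verified at every activity start time: the number of activities assigned
#' to unit `j` whose service interval `[b, b + d)` covers the start must not
#' exceed `k_j`. That is sufficient for all-times feasibility because
#' concurrency on a unit only increases at activity starts.
#'
#' @param instance a `careflow_instance`.
#' @param assignment data.table/data.frame with columns `act_id`, `unit_id`.
#' @param b numeric vector of start times (minutes), one per activity.
#' @param durations duration vector (minutes), one per activity.
#' @param tol numeric comparison tolerance (default 1e-6).
#' @return an object of class `careflow_feasibility`: list of violation
#'   tables by category (`assignment`, `release`, `precedence`, `capacity`)
#'   and a logical `feasible`. Reports, never raises.
#' @export
check_schedule <- function(instance, assignment, b, durations, tol = 1e-6) {
  acts <- instance$activities; pool <- instance$pool; V <- instance$V
  d <- as.numeric(durations)
  asg <- data.table::as.data.table(assignment)

  viol_assign <- data.table::data.table(act_id = integer(), type = character(),
                                        needed = integer(), got = integer())
  cnt <- asg[, .(n = .N),
             by = .(act_id, g = pool$type[match(unit_id, pool$unit_id)])]
  for (a in seq_len(nrow(acts))) for (gg in colnames(V)) {
    got <- cnt[act_id == a & g == gg, n]
    got <- if (length(got)) got else 0L
    if (got != V[a, gg])
      viol_assign <- rbind(viol_assign,
                           data.table::data.table(act_id = a, type = gg,
                                                  needed = V[a, gg], got = got))
  }

  ini <- which(acts$is_initial)
  late <- ini[b[ini] < acts$scheduled_time[ini] - tol]
  viol_release <- data.table::data.table(
    act_id = late, b = b[late], scheduled_time = acts$scheduled_time[late])

  a1 <- which(!acts$is_initial)
  pre <- acts$pre[a1]
  badp <- a1[b[a1] < b[pre] + d[pre] - tol]
  viol_prec <- data.table::data.table(
    act_id = badp, b = b[badp], pre = acts$pre[badp],
    pre_end = b[acts$pre[badp]] + d[acts$pre[badp]])

  viol_cap <- data.table::data.table(unit_id = character(), time = numeric(),
                                     concurrent = integer(), capacity = integer())
  for (u in unique(asg$unit_id)) {
    au <- asg[unit_id == u, act_id]
    k <- pool$capacity[match(u, pool$unit_id)]
    for (a in au) {
      tau <- b[a]
      nconc <- sum(b[au] <= tau + tol & b[au] + d[au] > tau + tol)
      if (nconc > k)
        viol_cap <- rbind(viol_cap, data.table::data.table(
          unit_id = u, time = tau, concurrent = nconc, capacity = k))
    }
  }
  viol_cap <- unique(viol_cap)

  structure(list(assignment = viol_assign, release = viol_release,
                 precedence = viol_prec, capacity = viol_cap,
                 feasible = nrow(viol_assign) + nrow(viol_release) +
                   nrow(viol_prec) + nrow(viol_cap) == 0),
            class = "careflow_feasibility")
}

#' @export
print.careflow_feasibility <- function(x, ...) {
  if (x$feasible) cat("schedule feasible: no violations\n")
  else {
    cat("schedule INFEASIBLE:\n")
    for (cat_name in c("assignment", "release", "precedence", "capacity"))
      if (nrow(x[[cat_name]]))
        cat(sprintf("  %s: %d violation(s)\n", cat_name, nrow(x[[cat_name]])))
  }
  invisible(x)
}
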