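## Internal model machinery for the two-stage formulation.
##
## First stage (scenario-free): binary assignment x[a,j], sequencing
## indicators s1[a,a'] ("a does not start before a'"), s2[a,a'] ("a starts
## before a' ends"), and concurrency indicators q[a,a',j], subject to
##   (1b) sum_{j in J_g} x[a,j] = V[a,g]
##   (1c) q >= s1 + s2 + x[a,j] + x[a',j] - 3
##   (1d) sum_{a'} q[a,a',j] <= k_j - 1.
## Second stage (per duration scenario n): continuous start times b with
##   (2b) b_a >= t_a                  (initial activities)
##   (2c) b_a >= b_pre(a) + d_pre(a)  (precedence)
##   (2d) M s1 >= b_a - b_a' + 1
##   (2e) M(1 - s1) >= b_a' - b_a
##   (2f) M s2 >= b_a' - b_a + d_a'
##   (2g) M(1 - s2) >= b_a - b_a' - d_a' + 1
## minimizing the average over scenarios of total waiting time.
## Pair variables exist only for ordered pairs sharing >= 1 required type.

## Variable layout for the SAA model with N scenarios.
saa_var_map <- function(instance, N) {
  acts <- instance$activities
  V <- instance$V
  pool <- instance$pool
  nA <- nrow(acts)
  req <- V > 0

  x_tab <- data.table::rbindlist(lapply(seq_len(nA), function(a) {
    g <- colnames(V)[req[a, ]]
    j <- which(pool$type %in% g)
    data.table::data.table(a = a, j = j)
  }))
  x_tab[, var := .I]
  nx <- nrow(x_tab)

  share <- tcrossprod(req) > 0        # TRUE if a, a2 share a required type
  diag(share) <- FALSE
  idx <- which(share, arr.ind = TRUE) # ordered pairs, both directions
  pair_tab <- data.table::data.table(a = idx[, 1], a2 = idx[, 2])
  data.table::setorder(pair_tab, a, a2)
  nP <- nrow(pair_tab)
  pair_tab[, p := .I]
  pair_tab[, s1var := nx + .I]
  pair_tab[, s2var := nx + nP + .I]

  q_tab <- if (nP > 0) data.table::rbindlist(lapply(seq_len(nP), function(p) {
    a <- pair_tab$a[p]; a2 <- pair_tab$a2[p]
    g <- colnames(V)[req[a, ] & req[a2, ]]
    data.table::data.table(p = p, a = a, a2 = a2,
                           j = which(pool$type %in% g))
  })) else data.table::data.table(p = integer(), a = integer(),
                                  a2 = integer(), j = integer())
  q_tab[, var := nx + 2L * nP + .I]
  nbin <- nx + 2L * nP + nrow(q_tab)

  list(acts = acts, pool = pool, V = V, nA = nA,
       x_tab = x_tab, pair_tab = pair_tab, q_tab = q_tab,
       nbin = nbin, b_off = nbin, N = N,
       nvar = nbin + N * nA,
       bvar = function(n, a) nbin + (n - 1L) * nA + a)
}

default_big_m <- function(instance, D) {
  t0 <- instance$activities$scheduled_time
  max(t0, na.rm = TRUE) + sum(apply(D, 2, max)) + 1
}

## Assemble the SAA MILP (objective, sparse triplets, bounds) for duration
## matrix D (N x |A|).
build_saa_model <- function(instance, D, cfg = solver_config()) {
  vm <- saa_var_map(instance, nrow(D))
  acts <- vm$acts; pool <- vm$pool
  N <- vm$N; nA <- vm$nA
  M <- cfg$big_m %||% default_big_m(instance, D)

  ti <- list(); tj <- list(); tx <- list()
  lb <- list(); ub <- list()
  nrowc <- 0L
  add <- function(i, j, x, l, u, nr) {
    k <- length(ti) + 1L
    ti[[k]] <<- i + nrowc; tj[[k]] <<- j; tx[[k]] <<- x
    lb[[k]] <<- l; ub[[k]] <<- u
    nrowc <<- nrowc + nr
  }

  ## (1b) assignment counts
  grp <- vm$x_tab[, .(vars = list(var)), by = .(a, g = pool$type[j])]
  r <- rep(seq_len(nrow(grp)), lengths(grp$vars))
  vreq <- instance$V[cbind(grp$a, match(grp$g, colnames(instance$V)))]
  add(r, unlist(grp$vars), rep(1, length(r)),
      l = vreq, u = vreq, nr = nrow(grp))

  pt <- vm$pair_tab; qt <- vm$q_tab
  if (nrow(qt)) {
    ## (1c) q - s1 - s2 - x[a,j] - x[a2,j] >= -3
    nq <- nrow(qt)
    xa <- vm$x_tab[qt, on = c(a = "a", j = "j"), var]
    xa2 <- vm$x_tab[qt, on = c(a = "a2", j = "j"), var]
    r <- rep(seq_len(nq), 5L)
    add(r,
        c(qt$var, pt$s1var[qt$p], pt$s2var[qt$p], xa, xa2),
        c(rep(1, nq), rep(-1, 4L * nq)),
        l = rep(-3, nq), u = rep(Inf, nq), nr = nq)

    ## (1d) capacity at starts: sum_a' q[a,a',j] <= k_j - 1
    cap_grp <- qt[, .(vars = list(var)), by = .(a, j)]
    r <- rep(seq_len(nrow(cap_grp)), lengths(cap_grp$vars))
    add(r, unlist(cap_grp$vars), rep(1, length(r)),
        l = rep(-Inf, nrow(cap_grp)),
        u = pool$capacity[cap_grp$j] - 1, nr = nrow(cap_grp))
  }

  ## (2c) precedence, all scenarios
  a1 <- which(!acts$is_initial)
  if (length(a1)) {
    pre <- acts$pre[a1]
    nn <- rep(seq_len(N), each = length(a1))
    aa <- rep(a1, N); pp <- rep(pre, N)
    r <- rep(seq_len(N * length(a1)), 2L)
    add(r, c(vm$bvar(nn, aa), vm$bvar(nn, pp)),
        c(rep(1, N * length(a1)), rep(-1, N * length(a1))),
        l = as.numeric(t(D[, pre, drop = FALSE])),
        u = rep(Inf, N * length(a1)), nr = N * length(a1))
  }

  nP <- nrow(pt)
  if (nP) {
    nn <- rep(seq_len(N), each = nP)
    pa <- rep(pt$a, N); pa2 <- rep(pt$a2, N)
    vs1 <- rep(pt$s1var, N); vs2 <- rep(pt$s2var, N)
    ba <- vm$bvar(nn, pa); ba2 <- vm$bvar(nn, pa2)
    da2 <- as.numeric(t(D[, pt$a2, drop = FALSE])) # scenario-major over pairs
    np <- N * nP
    r3 <- rep(seq_len(np), 3L)
    one <- rep(1, np); mone <- rep(-1, np)
    ## (2d) M s1 - b_a + b_a2 >= 1
    add(r3, c(vs1, ba, ba2), c(rep(M, np), mone, one),
        l = rep(1, np), u = rep(Inf, np), nr = np)
    ## (2e) -M s1 + b_a - b_a2 >= -M
    add(r3, c(vs1, ba, ba2), c(rep(-M, np), one, mone),
        l = rep(-M, np), u = rep(Inf, np), nr = np)
    ## (2f) M s2 + b_a - b_a2 >= d_a2
    add(r3, c(vs2, ba, ba2), c(rep(M, np), one, mone),
        l = da2, u = rep(Inf, np), nr = np)
    ## (2g) -M s2 - b_a + b_a2 >= 1 - M - d_a2
    add(r3, c(vs2, ba, ba2), c(rep(-M, np), mone, one),
        l = 1 - M - da2, u = rep(Inf, np), nr = np)
  }

  ## objective: average total waiting; b_a carries weight (1/N) only when no
  ## successor consumes it (telescoping of per-patient waits)
  w <- rep(1, nA)
  w[acts$pre[!is.na(acts$pre)]] <- 0
  obj <- numeric(vm$nvar)
  for (n in seq_len(N)) obj[vm$bvar(n, seq_len(nA))] <- w / N
  const <- -mean(vapply(seq_len(N), function(n) {
    sum(acts$scheduled_time[acts$is_initial]) +
      sum(D[n, acts$pre[!is.na(acts$pre)]])
  }, 1))

  var_lb <- numeric(vm$nvar)
  var_ub <- rep(Inf, vm$nvar)
  var_ub[seq_len(vm$nbin)] <- 1
  ## (2b) release times as bounds on b
  t0 <- ifelse(acts$is_initial, acts$scheduled_time, 0)
  for (n in seq_len(N)) var_lb[vm$bvar(n, seq_len(nA))] <- t0
  integrality <- c(rep(1L, vm$nbin), rep(0L, vm$nvar - vm$nbin))

  list(vm = vm, M = M, const = const,
       problem = list(nvar = vm$nvar, obj = obj,
                      A = list(i = unlist(ti), j = unlist(tj), x = unlist(tx)),
                      con_lb = unlist(lb), con_ub = unlist(ub),
                      var_lb = var_lb, var_ub = var_ub,
                      integrality = integrality,
                      mip_gap = cfg$mip_gap, time_limit = cfg$time_limit))
}

## Interpret a raw solver solution vector as a first-stage object.
extract_first_stage <- function(vm, sol) {
  xv <- round(sol[vm$x_tab$var])
  assignment <- vm$x_tab[xv > 0.5, .(act_id = a, unit_id = vm$pool$unit_id[j])]
  pairs <- vm$pair_tab[, .(a, a2, s1 = as.integer(round(sol[s1var])),
                           s2 = as.integer(round(sol[s2var])))]
  qdt <- vm$q_tab[, .(a, a2, unit_id = vm$pool$unit_id[j],
                      q = as.integer(round(sol[var])))]
  structure(list(assignment = assignment, pairs = pairs, q = qdt),
            class = "careflow_first_stage")
}

as_scenario_matrix <- function(scenarios, nA) {
  D <- if (is.matrix(scenarios)) scenarios else matrix(scenarios, nrow = 1)
  if (ncol(D) != nA)
    stop_cf("scenario matrix has %d columns but the instance has %d activities",
            ncol(D), nA)
  storage.mode(D) <- "double"
  D
}

#' Solve the sample average approximation model
#'
#' Builds and solves the SAA transformation of the two-stage model: the
#' first-stage assignment/sequencing constraints appear once, the
#' second-stage start-time constraints are replicated per duration scenario,
#' and the objective is the scenario-average total waiting time (minutes).
#' After the solver returns, start times are recomputed per scenario as the
#' earliest schedule consistent with the first-stage decisions (the least
#' element of the fixed-sequence constraint system), which removes arbitrary
#' slack the MILP may leave on intermediate activities; the reported `v_N`
#' is the average objective of these schedules.
#'
#' @param instance a `careflow_instance`.
#' @param scenarios a `careflow_scenarios` matrix (`N x |A|`) or a single
#'   duration vector.
#' @param cfg a [solver_config()].
#' @return an object of class `careflow_solution`: list with `first_stage`
#'   (assignment, sequencing pairs `s1`/`s2`, concurrency `q`),
#'   `realizations` (per scenario: start times `b`, per-activity `waits`,
#'   `objective`), `v_N`, `status` (`"optimal"` or `"time_limit"`),
#'   `mip_gap`, `milp_objective`, `big_m`, `solve_time` (seconds).
#' @seealso [solve_deterministic()], [evaluate_first_stage()],
#'   [check_schedule()]
#' @export
solve_saa <- function(instance, scenarios, cfg = solver_config()) {
  stopifnot(inherits(instance, "careflow_instance"))
  D <- as_scenario_matrix(scenarios, nrow(instance$activities))
  mod <- build_saa_model(instance, D, cfg)
  t0 <- proc.time()[["elapsed"]]
  res <- milp_solve_batch(list(mod$problem), cfg)[[1]]
  elapsed <- proc.time()[["elapsed"]] - t0
  if (res$status == 2L) {
    dump <- tempfile("careflow_infeasible_", fileext = ".lp")
    write_model_lp(mod$problem, dump)
    stop_cf("SAA model reported infeasible; this cannot occur for a valid instance. Model dumped to %s", dump)
  }
  if (is.null(res$x))
    stop_cf("solver returned no incumbent (status %d: %s)", res$status,
            res$message)
  sol <- as.numeric(unlist(res$x))
  fs <- extract_first_stage(mod$vm, sol)
  realizations <- lapply(seq_len(nrow(D)), function(n)
    schedule_fixed(instance, fs, D[n, ], relax = FALSE))
  vN <- mean(vapply(realizations, `[[`, 1, "objective"))
  structure(list(
    first_stage = fs,
    realizations = realizations,
    v_N = vN,
    status = if (res$status == 0L) "optimal" else "time_limit",
    mip_gap = res$mip_gap,
    milp_objective = res$objective + mod$const,
    big_m = mod$M,
    solve_time = elapsed,
    n_scenarios = nrow(D)
  ), class = "careflow_solution")
}

#' Solve the deterministic counterpart
#'
#' The deterministic model is the SAA model with a single duration scenario;
#' with the mean-value durations it is the mean-value baseline model.
#'
#' @param instance a `careflow_instance`.
#' @param durations a single-scenario `careflow_scenarios` matrix or a
#'   duration vector.
#' @param cfg a [solver_config()].
#' @return a `careflow_solution` (see [solve_saa()]) with one realization.
#' @export
solve_deterministic <- function(instance, durations, cfg = solver_config()) {
  D <- as_scenario_matrix(durations, nrow(instance$activities))
  if (nrow(D) != 1) stop_cf("deterministic solve expects a single scenario")
  solve_saa(instance, D, cfg)
}

#' @export
print.careflow_solution <- function(x, ...) {
  cat(sprintf(
    "careflow solution: v_N = %.4g min over %d scenario(s) [%s, gap %s, %.2fs]\n",
    x$v_N, x$n_scenarios, x$status,
    if (is.null(x$mip_gap)) "NA" else format(x$mip_gap, digits = 3),
    x$solve_time))
  invisible(x)
}

#' Dump a built model in CPLEX LP text format
#'
#' Debugging aid: writes the sparse model produced by the internal builder
#' in the standard LP file format so it can be inspected or fed to any
#' external solver.
#'
#' @param problem a problem list as built internally (fields `nvar`, `obj`,
#'   `A`, `con_lb`, `con_ub`, `var_lb`, `var_ub`, `integrality`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_lp <- function(problem, path) {
  con <- file(path, "w")
  on.exit(close(con))
  vn <- sprintf("x%d", seq_len(problem$nvar))
  nz <- which(problem$obj != 0)
  writeLines("Minimize", con)
  writeLines(paste(" obj:", paste(sprintf("%+g %s", problem$obj[nz], vn[nz]),
                                  collapse = " ")), con)
  writeLines("Subject To", con)
  A <- data.table::data.table(i = problem$A$i, j = problem$A$j, x = problem$A$x)
  data.table::setorder(A, i, j)
  terms <- A[, .(expr = paste(sprintf("%+g %s", x, vn[j]), collapse = " ")),
             by = i]
  for (k in seq_len(nrow(terms))) {
    i <- terms$i[k]
    l <- problem$con_lb[i]; u <- problem$con_ub[i]
    if (is.finite(l) && is.finite(u) && l == u)
      writeLines(sprintf(" c%d: %s = %g", i, terms$expr[k], l), con)
    else {
      if (is.finite(l))
        writeLines(sprintf(" c%dl: %s >= %g", i, terms$expr[k], l), con)
      if (is.finite(u))
        writeLines(sprintf(" c%du: %s <= %g", i, terms$expr[k], u), con)
    }
  }
  writeLines("Bounds", con)
  for (v in seq_len(problem$nvar)) {
    l <- problem$var_lb[v]; u <- problem$var_ub[v]
    writeLines(sprintf(" %s %s <= %s", if (is.finite(l)) sprintf("%g <=", l)
                       else "-inf <=", vn[v],
                       if (is.finite(u)) sprintf("%g", u) else "+inf"), con)
  }
  bin <- which(problem$integrality == 1L)
  if (length(bin)) {
    writeLines("General", con)
    writeLines(paste(" ", paste(vn[bin], collapse = " ")), con)
  }
  writeLines("End", con)
  invisible(path)
}
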