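#' Solver configuration
#'
#' Settings for the mixed-integer solver backend. Models are solved through
#' a branch-and-cut engine (HiGHS, reached via `scipy.optimize.milp`), so
#' every solution carries an optimality-gap certificate. The big-M constant
#' used to linearize the disjunctive sequencing constraints defaults to the
#' smallest easily-provable safe value for the instance and scenario set,
#' \eqn{M = \max_a t_a + \sum_a d^{max}_a + 1}; a custom value can be forced
#' with `big_m`.
#'
#' @param mip_gap relative MIP optimality gap tolerance (default 1e-4).
#' @param time_limit per-model time limit in seconds (default 3600).
#' @param big_m optional fixed big-M constant; `NULL` (default) computes the
#'   per-instance rule above.
#' @param python path to the python interpreter with scipy; found on the
#'   PATH by default.
#' @return an object of class `careflow_solver_config`.
#' @export
solver_config <- function(mip_gap = 1e-4, time_limit = 3600, big_m = NULL,
                          python = NULL) {
  stopifnot(mip_gap >= 0, time_limit > 0)
  if (!is.null(big_m)) stopifnot(big_m > 0)
  structure(list(mip_gap = mip_gap, time_limit = time_limit, big_m = big_m,
                 python = python),
            class = "careflow_solver_config")
}

find_python <- function(cfg = NULL) {
  if (!is.null(cfg$python)) return(cfg$python)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop_cf("no python interpreter found on the PATH (needed for the MILP backend)")
}

## Solve a batch of MILPs through the bundled scipy/HiGHS helper.
## Each problem: list(nvar, obj, A = list(i, j, x), con_lb, con_ub,
## var_lb, var_ub, integrality, mip_gap, time_limit). Infinities are
## encoded as +/- 1e30.
milp_solve_batch <- function(problems, cfg = solver_config()) {
  script <- system.file("python", "milp_solve.py", package = "careflow")
  if (!nzchar(script)) stop_cf("bundled solver helper not found; is careflow installed?")
  enc <- function(p) {
    cap <- function(v) {
      v[is.infinite(v) & v > 0] <- 1e30
      v[is.infinite(v) & v < 0] <- -1e30
      v
    }
    p$con_lb <- cap(p$con_lb); p$con_ub <- cap(p$con_ub)
    p$var_lb <- cap(p$var_lb); p$var_ub <- cap(p$var_ub)
    p$mip_gap <- p$mip_gap %||% cfg$mip_gap
    p$time_limit <- p$time_limit %||% cfg$time_limit
    p
  }
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(list(problems = lapply(problems, enc)), fin,
                       auto_unbox = TRUE, digits = NA)
  status <- system2(find_python(cfg), c(shQuote(script), shQuote(fin),
                                        shQuote(fout)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0L || !file.exists(fout))
    stop_cf("MILP backend failed (exit %s):\n%s", code,
            paste(status, collapse = "\n"))
  jsonlite::read_json(fout, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}
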