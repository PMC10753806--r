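# ---------------------------------------------------------------------------
# Benchmark harness: runs the solvers over a sweep of generated problems
# from identical guesses and records iteration counts, residual histories
# and instrumented operation counts.  Wall-clock times are recorded for
# information only; they are hardware-dependent and deliberately excluded
# from every comparison the package makes.
# ---------------------------------------------------------------------------

#' Run a solver-comparison experiment
#'
#' For every combination of `kind`, `n`, `n_eig` and seed, generates the
#' problem, builds one shared start guess, runs each requested algorithm
#' from that guess and records iteration counts, convergence status,
#' per-iteration residual histories and operation counters.  Solver
#' failures (e.g. SSF breakdown on barely diagonally dominant problems)
#' are recorded as such, not fatal.
#'
#' @param kinds character vector of problem kinds (see [gen_problem()]).
#' @param ns integer vector of problem half-dimensions.
#' @param n_eigs integer vector of root counts.
#' @param algos character vector from `"smogd"`, `"olsen"`, `"ssf"`.
#' @param seeds integer vector of generator seeds.
#' @param tol_rms,tol_max,max_space_per_root,max_iter,guess_perturb solver
#'   settings shared by all cells (see [solver_config()]).
#' @param out optional path for a JSON report.
#' @return a data frame with one row per (cell, algorithm): iteration
#'   count, status, converged roots, MVP batches/columns, operation
#'   counters and wall time.  The full reports are attached as the
#'   `"reports"` attribute.
#' @export
run_experiment <- function(kinds = "tddft", ns = 200L, n_eigs = 5L,
                           algos = c("smogd", "ssf"), seeds = 1:3,
                           tol_rms = 1e-6, tol_max = 1e-5,
                           max_space_per_root = 20L, max_iter = 100L,
                           guess_perturb = 0.01, out = NULL) {
  rows <- list()
  reports <- list()
  for (kind in kinds) for (n in ns) for (ne in n_eigs) for (sd in seeds) {
    prob <- gen_problem(n, seed = sd, kind = kind)
    cfgs <- solver_config(ne, tol_rms = tol_rms, tol_max = tol_max,
                          max_space_per_root = max_space_per_root,
                          max_iter = max_iter, seed = sd,
                          guess_perturb = guess_perturb)
    guess <- gen_guess(prob, ne, perturb = guess_perturb, seed = sd)
    for (algo in algos) {
      if (algo == "ssf" && !prob$is_tddft) next
      t0 <- proc.time()[["elapsed"]]
      rep_ <- tryCatch(solve_response(prob, cfgs, algo, guess = guess),
                       linresp_error = function(e) e,
                       error = function(e) e)
      wall <- proc.time()[["elapsed"]] - t0
      key <- sprintf("%s_n%d_k%d_s%d_%s", kind, n, ne, sd, algo)
      failed <- inherits(rep_, "condition")
      rows[[key]] <- data.frame(
        kind = kind, n = n, n_eig = ne, seed = sd, algorithm = algo,
        status = if (failed) paste0("error: ", conditionMessage(rep_)) else rep_$status,
        iterations = if (failed) NA_integer_ else rep_$iterations,
        n_converged = if (failed) 0L else sum(rep_$converged),
        mvp_batches = if (failed) NA_integer_ else rep_$mvp_batches,
        mvp_cols = if (failed) NA_integer_ else rep_$mvp_cols,
        ev_m = if (failed) NA_integer_ else rep_$counters$ev_m,
        mm_m = if (failed) NA_integer_ else rep_$counters$mm_m,
        svd_m = if (failed) NA_integer_ else rep_$counters$svd_m,
        chol_m = if (failed) NA_integer_ else rep_$counters$chol_m,
        max_sweeps = if (failed) NA_integer_ else rep_$counters$max_sweeps,
        wall_s = wall,
        stringsAsFactors = FALSE)
      reports[[key]] <- rep_
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(out)) {
    keep <- res
    jsonlite::write_json(keep, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  attr(res, "reports") <- reports
  res
}
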