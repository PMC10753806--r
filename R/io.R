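# ---------------------------------------------------------------------------
# Matrix Market + JSON manifest I/O for dense-backed problems, and JSONL
# iteration logging.
# ---------------------------------------------------------------------------

#' Write a dense-backed problem as Matrix Market files with a manifest
#'
#' Writes `ApB.mtx`, `AmB.mtx`, `Sigma.mtx` (symmetric storage) and
#' `Delta.mtx` (general storage; the Matrix Market format has no
#' antisymmetric tag commonly honoured by readers) plus a
#' `manifest.json` recording the file names, `n` and the TD-DFT flag.
#' For TD-DFT problems the metric files are omitted.
#'
#' @param problem a dense-backed [response_problem()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_problem <- function(problem, dir) {
  if (is.null(problem$dense)) stop("only dense-backed problems can be written")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- problem$dense
  wr_sym <- function(M, f) {
    Ms <- methods::as(methods::as(Matrix::forceSymmetric(Matrix::Matrix(M)),
                                  "generalMatrix"), "CsparseMatrix")
    Ms <- Matrix::forceSymmetric(Ms)
    Matrix::writeMM(Ms, file.path(dir, f))
  }
  wr_gen <- function(M, f) {
    ## general coordinate storage, written directly: writeMM would tag
    ## Delta as skew-symmetric, which many Matrix Market readers (including
    ## Matrix::readMM) do not accept
    idx <- which(M != 0, arr.ind = TRUE)
    con <- file(file.path(dir, f), "wt")
    on.exit(close(con))
    writeLines("%%MatrixMarket matrix coordinate real general", con)
    writeLines(sprintf("%d %d %d", nrow(M), ncol(M), nrow(idx)), con)
    writeLines(sprintf("%d %d %.17g", idx[, 1], idx[, 2], M[idx]), con)
  }
  wr_sym(d$ApB, "ApB.mtx")
  wr_sym(d$AmB, "AmB.mtx")
  files <- list(ApB = "ApB.mtx", AmB = "AmB.mtx")
  if (!problem$is_tddft) {
    wr_sym(d$Sigma, "Sigma.mtx")
    wr_gen(d$Delta, "Delta.mtx")
    files$Sigma <- "Sigma.mtx"
    files$Delta <- "Delta.mtx"
  }
  manifest <- list(n = problem$n, is_tddft = problem$is_tddft, files = files)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a problem from a Matrix Market manifest
#'
#' @param manifest path to a `manifest.json` written by [write_problem()].
#' @param check verify the operator contract after reading.
#' @return a dense-backed [response_problem()].
#' @export
read_problem <- function(manifest, check = TRUE) {
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  rd <- function(f) as.matrix(Matrix::readMM(file.path(dir, f)))
  ApB <- rd(man$files$ApB)
  AmB <- rd(man$files$AmB)
  if (isTRUE(man$is_tddft))
    return(dense_response_problem(ApB, AmB, check = check))
  dense_response_problem(ApB, AmB, rd(man$files$Sigma), rd(man$files$Delta),
                         check = check)
}

#' Write a JSONL iteration log for a solve report
#'
#' One record per iteration (subspace size, per-root eigenvalue and
#' residual norms, instrumentation deltas) followed by a final record with
#' the converged eigenvalues and counter totals.
#'
#' @param report a `solve_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_iteration_log <- function(report, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(report$iterations)) {
    rec <- list(iter = i,
                omega = unname(report$ritz_history[i, ]),
                rms = unname(report$rms_history[i, ]),
                maxabs = unname(report$max_history[i, ]))
    if (!is.null(report$iter_log))
      rec <- c(rec, as.list(report$iter_log[i, setdiff(names(report$iter_log), "iter")]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  final <- list(final = TRUE, algorithm = report$algorithm,
                status = report$status, iterations = report$iterations,
                omega = unname(report$omegas),
                converged = unname(report$converged),
                mvp_batches = report$mvp_batches, mvp_cols = report$mvp_cols,
                counters = report$counters)
  writeLines(jsonlite::toJSON(final, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Solve a response problem with a named algorithm
#'
#' Thin dispatcher over [smogd_solve()], [olsen_solve()] and
#' [ssf_solve()].
#'
#' @param problem a [response_problem()].
#' @param config a [solver_config()].
#' @param algo one of `"smogd"`, `"olsen"`, `"ssf"`.
#' @param guess optional start guess.
#' @return a `solve_report`.
#' @export
solve_response <- function(problem, config, algo = c("smogd", "olsen", "ssf"),
                           guess = NULL) {
  algo <- match.arg(algo)
  switch(algo,
         smogd = smogd_solve(problem, config, guess),
         olsen = olsen_solve(problem, config, guess),
         ssf = ssf_solve(problem, config, guess))
}
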