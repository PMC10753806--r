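# ---------------------------------------------------------------------------
# Shared solver machinery: configuration, instrumentation counters, the
# per-coordinate 2x2 diagonal preconditioner, convergence bookkeeping and
# the solve report container.
# ---------------------------------------------------------------------------

#' Solver configuration
#'
#' @param n_eig number of eigenpairs sought (smallest positive
#'   excitation energies).
#' @param tol_rms convergence threshold on the root-mean-square norm of
#'   the full-space residual \eqn{\Lambda x - \omega \Omega x} (RMS taken
#'   over all `2n` components, per root, with `x` normalized to unit
#'   coefficient norm in a response-metric-orthonormal basis).
#' @param tol_max convergence threshold on the max-abs component of the
#'   same residual.
#' @param max_space_per_root subspace cap: at most
#'   `max_space_per_root * n_eig` expansion vectors per parity are kept; a
#'   thick restart collapses the space onto the current Ritz vectors when
#'   the cap would be exceeded.
#' @param max_iter maximum number of outer iterations.
#' @param precond_floor floor applied to the per-coordinate 2x2
#'   preconditioner determinant.
#' @param seed seed used for the start guess noise.
#' @param guess_perturb amplitude of uniform noise added to the canonical
#'   start guess (see [gen_guess()]).
#' @param ortho an [ortho_config()].
#' @return list of class `solver_config`.
#' @export
solver_config <- function(n_eig, tol_rms = 1e-6, tol_max = 1e-5,
                          max_space_per_root = 20L, max_iter = 100L,
                          precond_floor = 1e-8, seed = 1L,
                          guess_perturb = 0, ortho = ortho_config()) {
  stopifnot(n_eig >= 1L, tol_rms > 0, tol_max > 0, max_space_per_root >= 2L,
            max_iter >= 1L, precond_floor > 0)
  structure(list(n_eig = as.integer(n_eig), tol_rms = tol_rms,
                 tol_max = tol_max,
                 max_space_per_root = as.integer(max_space_per_root),
                 max_iter = as.integer(max_iter),
                 precond_floor = precond_floor, seed = as.integer(seed),
                 guess_perturb = guess_perturb, ortho = ortho),
            class = "solver_config")
}

## Fresh instrumentation counter environment.  *_m counts m-sized dense
## linear algebra (m = subspace dimension); chol_small counts the
## n_eig-sized Cholesky factorizations used by the orthogonalization
## primitives; chol_2m/ev_2m are the 2m-sized operations of the Olsen
## reduced solve.
new_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$ev_m <- 0L; e$mm_m <- 0L; e$svd_m <- 0L; e$chol_m <- 0L
  e$chol_2m <- 0L; e$ev_2m <- 0L
  e$chol_small <- 0L; e$max_sweeps <- 0L
  e
}

counter_snapshot <- function(cnt) {
  list(ev_m = cnt$ev_m, mm_m = cnt$mm_m, svd_m = cnt$svd_m,
       chol_m = cnt$chol_m, chol_2m = cnt$chol_2m, ev_2m = cnt$ev_2m,
       chol_small = cnt$chol_small, max_sweeps = cnt$max_sweeps)
}

## Coordinate-wise solve of [[a, c], [c, a]] (b+, b-) = -(R+, R-) for every
## coordinate and every root column.  `a` and `c` are n x p matrices (or
## vectors recycled per root).  Determinants smaller than `floor` in
## magnitude are replaced by sign(det) * floor, sign(0) = +1, so the solve
## never breaks down.
precond_2x2 <- function(a, c_, Rp, Rm, floor_) {
  det <- a * a - c_ * c_
  s <- ifelse(det >= 0, 1, -1)
  det <- ifelse(abs(det) < floor_, s * floor_, det)
  list(plus = (-a * Rp + c_ * Rm) / det,
       minus = (c_ * Rp - a * Rm) / det)
}

## Per-root residual norms in the conventions used for convergence: the
## full-space residual has top half R+ + R- and bottom half R+ - R-, so
## the RMS over 2n components is sqrt((|R+|^2 + |R-|^2) / n).
residual_norms <- function(Rp, Rm, n) {
  rms <- sqrt((colSums(Rp^2) + colSums(Rm^2)) / n)
  mx <- pmax(apply(abs(Rp + Rm), 2, max), apply(abs(Rp - Rm), 2, max))
  list(rms = rms, maxabs = mx)
}

## Assemble full-space eigenvectors from reduced coefficients, normalize
## each root to x' Omega x = 1 (positive at convergence) and fix the sign
## so the largest-magnitude component of (y, z) is positive.  `q` is the
## vector of Omega-bilinear values per root.
assemble_vectors <- function(x_plus, x_minus, q) {
  for (j in seq_len(ncol(x_plus))) {
    if (is.finite(q[j]) && q[j] > 0) {
      sc <- 1 / sqrt(q[j])
      x_plus[, j] <- x_plus[, j] * sc
      x_minus[, j] <- x_minus[, j] * sc
    }
    full <- c(x_plus[, j] + x_minus[, j], x_plus[, j] - x_minus[, j])
    if (full[which.max(abs(full))] < 0) {
      x_plus[, j] <- -x_plus[, j]
      x_minus[, j] <- -x_minus[, j]
    }
  }
  list(y = x_plus + x_minus, z = x_plus - x_minus,
       x_plus = x_plus, x_minus = x_minus)
}

make_report <- function(algorithm, problem, config, omegas, converged,
                        vectors, iterations, status, ritz_history,
                        rms_history, max_history, iter_log, counter,
                        mvp_start, mvp_guess) {
  mvp_end <- mvp_counters(problem)
  structure(list(
    algorithm = algorithm,
    n = problem$n,
    n_eig = config$n_eig,
    omegas = omegas,
    converged = converged,
    y = vectors$y, z = vectors$z,
    x_plus = vectors$x_plus, x_minus = vectors$x_minus,
    iterations = iterations,
    status = status,
    ritz_history = ritz_history,
    rms_history = rms_history,
    max_history = max_history,
    iter_log = iter_log,
    counters = counter_snapshot(counter),
    mvp_batches = mvp_end$mvp_batches - mvp_start$mvp_batches,
    mvp_cols = mvp_end$mvp_cols - mvp_start$mvp_cols,
    mvp_batches_guess = mvp_guess$batches,
    mvp_cols_guess = mvp_guess$cols,
    config = config
  ), class = "solve_report")
}

#' @export
print.solve_report <- function(x, ...) {
  cat(sprintf("<solve_report> %s: n = %d, %d roots, %d iterations (%s)\n",
              x$algorithm, x$n, x$n_eig, x$iterations, x$status))
  cat("  omega:", format(x$omegas, digits = 8), "\n")
  cat(sprintf("  converged: %d/%d; MVP batches %d (columns %d)\n",
              sum(x$converged), x$n_eig, x$mvp_batches, x$mvp_cols))
  cc <- x$counters
  cat(sprintf("  m-sized ops: EV %d, MM %d, SVD %d, CD %d; small CD %d; max sweeps %d\n",
              cc$ev_m, cc$mm_m, cc$svd_m, cc$chol_m, cc$chol_small, cc$max_sweeps))
  invisible(x)
}

## Euclidean Cholesky orthonormalization that co-transforms stored image
## blocks (used by thick restarts, where images must follow the basis
## without new operator applications).
euclid_orthonormalize_with <- function(W, extras, cfg, counter = NULL) {
  for (sweep in seq_len(cfg$max_sweeps)) {
    M <- crossprod(W)
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) {
      Ms <- M + diag(cfg$chol_retry_shift * max(diag(M)), ncol(M))
      R <- tryCatch(chol(Ms), error = function(e) NULL)
    }
    if (!is.null(counter)) counter$chol_small <- counter$chol_small + 1L
    if (is.null(R))
      stop("rank-deficiency: restart basis overlap not positive definite")
    Ri <- backsolve(R, diag(ncol(W)))
    W <- W %*% Ri
    extras <- lapply(extras, function(X) X %*% Ri)
    if (max(abs(crossprod(W) - diag(ncol(W)))) < cfg$proj_threshold) break
  }
  c(list(W = W), extras)
}

solver_error <- function(class_, msg) {
  stop(structure(class = c(class_, "linresp_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
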