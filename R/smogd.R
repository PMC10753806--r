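# ---------------------------------------------------------------------------
# SMO-GD: Swapped-Metric-Orthogonal Generalized Davidson.
#
# The response problem Lambda x = omega Omega x has an indefinite metric
# Omega, but under ground-state stability Lambda is SPD, so the swapped
# form Omega x = (1/omega) Lambda x is a generalized eigenproblem with an
# SPD metric.  Expanding x in symmetric/antisymmetric vectors that are
# orthonormal in the Lambda inner product turns the reduced problem into
#     [[0, S], [S', 0]] u = (1/omega) u,    S_ij = (b_i^+)' (Sigma-Delta) b_j^-
# which is solved through the half-size SPD eigenproblem
#     S S' u+ = (1/omega^2) u+,   u- = omega S' u+.
# Per iteration the only m-sized dense operations are the product S S' and
# one symmetric diagonalization.
# ---------------------------------------------------------------------------

## Internal subspace container.
##   Vp/Vm   : n x m expansion blocks (Lambda-orthonormal per parity)
##   LVp/LVm : stored images (A+B)Vp, (A-B)Vm  ("sigma" vectors)
##   BVp/BVm : stored images (Sigma+Delta)Vp, (Sigma-Delta)Vm  ("tau")
##   S       : reduced coupling matrix Vp' BVm
new_subspace <- function(n) {
  z <- matrix(0, n, 0)
  list(Vp = z, Vm = z, LVp = z, LVm = z, BVp = z, BVm = z,
       S = matrix(0, 0, 0))
}

#' Solve the SMO-GD reduced problem
#'
#' Given the reduced coupling matrix `S` of a response-metric-orthonormal
#' subspace, forms `S S'` (one m-sized matrix-matrix multiply),
#' diagonalizes it (one m-sized symmetric diagonalization) and returns the
#' `n_eig` smallest excitation energies \eqn{\omega = 1/\sqrt{\mu}} from
#' the largest eigenvalues \eqn{\mu} of `S S'`, with `u_plus` the
#' corresponding orthonormal eigenvectors and `u_minus = omega * S' u_plus`.
#'
#' @param S reduced coupling matrix (`m+ x m-`).
#' @param n_eig number of roots.
#' @param counter optional instrumentation environment.
#' @return list with `omegas` (ascending, positive), `u_plus`, `u_minus`.
#' @export
solve_reduced <- function(S, n_eig, counter = NULL) {
  if (!all(is.finite(S))) solver_error("linresp_instability", "reduced matrix not finite")
  if (nrow(S) < n_eig || ncol(S) < n_eig)
    stop("reduced space smaller than the number of requested roots")
  SSt <- tcrossprod(S)
  if (!is.null(counter)) counter$mm_m <- counter$mm_m + 1L
  es <- eigen((SSt + t(SSt)) / 2, symmetric = TRUE)
  if (!is.null(counter)) counter$ev_m <- counter$ev_m + 1L
  mu <- es$values[seq_len(n_eig)]
  if (any(mu <= 0))
    solver_error("linresp_instability",
                 "nonpositive reduced eigenvalue: stability assumption violated or subspace degenerate")
  omegas <- 1 / sqrt(mu)
  u_plus <- es$vectors[, seq_len(n_eig), drop = FALSE]
  u_minus <- crossprod(S, u_plus)
  u_minus <- sweep(u_minus, 2, omegas, `*`)
  list(omegas = omegas, u_plus = u_plus, u_minus = u_minus)
}

#' Residual of the swapped-form problem from stored images
#'
#' Computes, entirely from the stored operator images (no new operator
#' applications), the parity components of
#' \eqn{R = \Omega x - (1/\omega) \Lambda x}:
#' `R+ = BVm u- - (1/omega) LVp u+` and `R- = BVp u+ - (1/omega) LVm u-`.
#'
#' @param state subspace state (internal; exposed for testing).
#' @param omegas,u_plus,u_minus current Ritz approximations.
#' @return a [parity_block()] with one column per root.
#' @export
form_residual <- function(state, omegas, u_plus, u_minus) {
  inv <- 1 / omegas
  Rp <- state$BVm %*% u_minus - sweep(state$LVp %*% u_plus, 2, inv, `*`)
  Rm <- state$BVp %*% u_plus - sweep(state$LVm %*% u_minus, 2, inv, `*`)
  parity_block(Rp, Rm)
}

#' Diagonal preconditioner of the swapped-form residual
#'
#' Solves, independently for each coordinate `i` and root, the 2x2 system
#' \deqn{\begin{pmatrix} -D_{A,i}/\omega & D_{\Sigma,i} \\
#'        D_{\Sigma,i} & -D_{A,i}/\omega \end{pmatrix}
#'       \begin{pmatrix} b^+_i \\ b^-_i \end{pmatrix} =
#'       -\begin{pmatrix} R^+_i \\ R^-_i \end{pmatrix},}
#' the parity split of the diagonal approximation to
#' \eqn{(\Omega - \Lambda/\omega) b = -R} (the diagonal of \eqn{\Lambda}
#' preserves parity while the diagonal of \eqn{\Omega} swaps it).
#' Determinants smaller than `floor` in magnitude are floored.
#'
#' @param diag_A,diag_Sigma length-`n` diagonals of `A` and `Sigma`.
#' @param omegas per-root eigenvalue estimates (positive).
#' @param R residual [parity_block()], one column per root.
#' @param floor determinant floor (default `1e-8`).
#' @return a [parity_block()] of new candidate directions.
#' @export
precondition <- function(diag_A, diag_Sigma, omegas, R, floor = 1e-8) {
  p <- length(omegas)
  a <- -outer(diag_A, 1 / omegas)        # n x p
  c_ <- matrix(diag_Sigma, length(diag_Sigma), p)
  b <- precond_2x2(a, c_, R$plus, R$minus, floor)
  parity_block(b$plus, b$minus)
}

## Enlarge the Lambda-orthonormal subspace with candidate directions.
## Per parity: project against the existing block in the Lambda inner
## product (using the stored images, no MVPs), Cholesky-orthonormalize,
## apply A+-B to the survivors (the iteration's only response-matrix
## MVPs), Lambda-orthonormalize with consistent image transformation,
## then apply Sigma+-Delta (or copy, for TD-DFT) and extend S by the new
## row/column blocks.
smogd_expand <- function(state, cand, problem, cfg, counter) {
  pu_p <- purify_candidates(state$Vp, cand$plus, images = state$LVp,
                            cfg = cfg, counter = counter)
  pu_m <- purify_candidates(state$Vm, cand$minus, images = state$LVm,
                            cfg = cfg, counter = counter)
  Wp <- pu_p$W; Wm <- pu_m$W
  added <- c(ncol(Wp), ncol(Wm))
  if (all(added == 0L)) return(list(state = state, added = added))

  if (ncol(Wp) > 0L) {
    LWp <- apply_op(problem, "ApB", Wp)
    mo <- metric_orthonormalize(Wp, LWp, cfg = cfg, counter = counter)
    Wp <- mo$W; LWp <- mo$LW
    BWp <- if (problem$is_tddft) Wp else apply_op(problem, "SpD", Wp)
  }
  if (ncol(Wm) > 0L) {
    LWm <- apply_op(problem, "AmB", Wm)
    mo <- metric_orthonormalize(Wm, LWm, cfg = cfg, counter = counter)
    Wm <- mo$W; LWm <- mo$LW
    BWm <- if (problem$is_tddft) Wm else apply_op(problem, "SmD", Wm)
  }

  ## extend S = Vp' BVm by the new blocks only
  S <- state$S
  if (ncol(Wm) > 0L) S <- cbind(S, crossprod(state$Vp, BWm))
  if (ncol(Wp) > 0L) {
    right <- if (ncol(Wm) > 0L) cbind(state$BVm, BWm) else state$BVm
    S <- rbind(S, crossprod(Wp, right))
  }
  if (ncol(Wp) > 0L) {
    state$Vp <- cbind(state$Vp, Wp)
    state$LVp <- cbind(state$LVp, LWp)
    state$BVp <- cbind(state$BVp, BWp)
  }
  if (ncol(Wm) > 0L) {
    state$Vm <- cbind(state$Vm, Wm)
    state$LVm <- cbind(state$LVm, LWm)
    state$BVm <- cbind(state$BVm, BWm)
  }
  state$S <- S
  list(state = state, added = added)
}

## Thick restart: collapse each parity block onto the current Ritz
## components, re-orthonormalized in the Lambda inner product; images are
## transformed consistently (no new MVPs) and S is recomputed from them.
smogd_restart <- function(state, u_plus, u_minus, cfg, counter) {
  collapse <- function(V, LV, BV, U) {
    X <- V %*% U; LX <- LV %*% U; BX <- BV %*% U
    eo <- euclid_orthonormalize_with(X, list(LX = LX, BX = BX), cfg, counter)
    mo <- metric_orthonormalize(eo$W, eo$LX, extra = list(BX = eo$BX),
                                cfg = cfg, counter = counter)
    list(V = mo$W, LV = mo$LW, BV = mo$BX)
  }
  p <- collapse(state$Vp, state$LVp, state$BVp, u_plus)
  m <- collapse(state$Vm, state$LVm, state$BVm, u_minus)
  state$Vp <- p$V; state$LVp <- p$LV; state$BVp <- p$BV
  state$Vm <- m$V; state$LVm <- m$LV; state$BVm <- m$BV
  state$S <- crossprod(state$Vp, state$BVm)
  state
}

#' Solve the response problem with the SMO-GD algorithm
#'
#' Runs the Swapped-Metric-Orthogonal Generalized Davidson iteration:
#' canonical (optionally perturbed) start guess, reduced solve through the
#' half-size symmetric eigenproblem, residual check against `tol_rms` and
#' `tol_max`, locking of converged roots, diagonal preconditioning,
#' response-metric-orthogonal subspace expansion, and thick restart at the
#' subspace cap.  Converged eigenvectors are normalized to
#' \eqn{x^T \Omega x = 1} with the largest-magnitude component positive.
#'
#' A root counts as converged when the full-space residual
#' \eqn{\Lambda x - \omega \Omega x} (with `x` at unit coefficient norm in
#' the metric-orthonormal basis) has RMS below `tol_rms` and max-abs below
#' `tol_max`; the same convention is used by all solvers in the package so
#' iteration counts are directly comparable.
#'
#' @param problem a [response_problem()].
#' @param config a [solver_config()].
#' @param guess optional [parity_block()] start guess; defaults to
#'   [gen_guess()] with the config's `guess_perturb` and `seed`.
#' @return a `solve_report` with eigenvalues (ascending), assembled
#'   eigenvectors `y`, `z`, per-iteration Ritz/residual histories and
#'   instrumentation counters.
#' @export
smogd_solve <- function(problem, config, guess = NULL) {
  n <- problem$n; n_eig <- config$n_eig
  if (2L * n_eig > n) stop("need n_eig * 2 <= n")
  cfg <- config$ortho
  counter <- new_counter()
  mvp_start <- mvp_counters(problem)
  if (is.null(guess))
    guess <- gen_guess(problem, n_eig, perturb = config$guess_perturb,
                       seed = config$seed)

  state <- new_subspace(n)
  ex <- smogd_expand(state, guess, problem, cfg, counter)
  if (any(ex$added < n_eig))
    stop("start guess is rank-deficient: fewer independent vectors than roots")
  state <- ex$state
  mvp_after_guess <- mvp_counters(problem)
  mvp_guess <- list(batches = mvp_after_guess$mvp_batches - mvp_start$mvp_batches,
                    cols = mvp_after_guess$mvp_cols - mvp_start$mvp_cols)

  cap <- config$max_space_per_root * n_eig
  ritz_hist <- rms_hist <- max_hist <- NULL
  iter_log <- list()
  status <- "max_iter"
  converged <- rep(FALSE, n_eig)
  red <- NULL
  prev_snap <- counter_snapshot(counter)
  prev_mvp <- mvp_counters(problem)

  for (iter in seq_len(config$max_iter)) {
    red <- solve_reduced(state$S, n_eig, counter)
    omg <- red$omegas

    ## unit coefficient norm per root (basis is Lambda-orthonormal)
    cs <- sqrt(colSums(red$u_plus^2) + colSums(red$u_minus^2))
    uPn <- sweep(red$u_plus, 2, cs, `/`)
    uMn <- sweep(red$u_minus, 2, cs, `/`)
    Rsw <- form_residual(state, omg, uPn, uMn)
    ## standard-form residual Lambda x - omega Omega x = -omega * R_swapped
    Rp <- sweep(Rsw$plus, 2, omg, `*`)
    Rm <- sweep(Rsw$minus, 2, omg, `*`)
    nr <- residual_norms(Rp, Rm, n)
    converged <- nr$rms < config$tol_rms & nr$maxabs < config$tol_max

    ritz_hist <- rbind(ritz_hist, omg)
    rms_hist <- rbind(rms_hist, nr$rms)
    max_hist <- rbind(max_hist, nr$maxabs)
    snap <- counter_snapshot(counter); mvp_now <- mvp_counters(problem)
    iter_log[[iter]] <- data.frame(
      iter = iter, m_plus = ncol(state$Vp), m_minus = ncol(state$Vm),
      n_converged = sum(converged),
      mvp_batches = mvp_now$mvp_batches - prev_mvp$mvp_batches,
      mvp_cols = mvp_now$mvp_cols - prev_mvp$mvp_cols,
      ev_m = snap$ev_m - prev_snap$ev_m,
      mm_m = snap$mm_m - prev_snap$mm_m,
      svd_m = snap$svd_m - prev_snap$svd_m,
      chol_m = snap$chol_m - prev_snap$chol_m,
      chol_small = snap$chol_small - prev_snap$chol_small)
    prev_snap <- snap; prev_mvp <- mvp_now

    if (all(converged)) { status <- "converged"; break }
    if (iter == config$max_iter) break

    active <- which(!converged)          # locking: converged roots expand nothing
    cand <- precondition(problem$diag_A, problem$diag_Sigma, omg[active],
                         parity_block(Rsw$plus[, active, drop = FALSE],
                                      Rsw$minus[, active, drop = FALSE]),
                         floor = config$precond_floor)
    if (ncol(state$Vp) + length(active) > cap ||
        ncol(state$Vm) + length(active) > cap)
      state <- smogd_restart(state, red$u_plus, red$u_minus, cfg, counter)
    ex <- smogd_expand(state, cand, problem, cfg, counter)
    if (all(ex$added == 0L))
      solver_error("linresp_stagnation",
                   "stagnation: all candidate directions linearly dependent and no root converged")
    state <- ex$state
  }

  xP <- state$Vp %*% red$u_plus
  xM <- state$Vm %*% red$u_minus
  q <- 4 * colSums(red$u_plus * (state$S %*% red$u_minus))
  vecs <- assemble_vectors(xP, xM, q)
  rownames(ritz_hist) <- rownames(rms_hist) <- rownames(max_hist) <- NULL
  make_report("smogd", problem, config, red$omegas, converged, vecs,
              nrow(ritz_hist), status, ritz_hist, rms_hist, max_hist,
              do.call(rbind, iter_log), counter, mvp_start, mvp_guess)
}
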