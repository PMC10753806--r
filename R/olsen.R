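# ---------------------------------------------------------------------------
# Olsen reduced-space solver (the classic paired-Davidson algorithm).
#
# Expansion vectors are kept Euclidean-orthonormal per parity, so the
# projected problem retains reduced response blocks E+- as a metric:
#     [[0, S], [S', 0]] u = (1/omega) diag(E+, E-) u
# solved, per the swapped prescription, as a symmetric-definite
# generalized eigenproblem of size 2m (one 2m Cholesky factorization of
# the metric plus one 2m symmetric diagonalization per iteration).
# ---------------------------------------------------------------------------

#' Solve the Olsen reduced problem
#'
#' Solves `[[0, S], [S', 0]] u = (1/omega) diag(E_plus, E_minus) u` as a
#' symmetric-definite generalized eigenproblem (Cholesky of the SPD
#' reduced metric followed by a symmetric diagonalization) and returns the
#' `n_eig` largest values of \eqn{1/\omega}, i.e. the smallest positive
#' excitation energies.
#'
#' @param E_plus,E_minus reduced response blocks
#'   \eqn{E^\pm_{ij} = (b_i^\pm)^T (A \pm B) b_j^\pm}, symmetric positive
#'   definite.
#' @param S reduced coupling matrix.
#' @param n_eig number of roots.
#' @param counter optional instrumentation environment.
#' @return list with `omegas` (ascending), `u_plus`, `u_minus`.
#' @export
olsen_solve_reduced <- function(E_plus, E_minus, S, n_eig, counter = NULL) {
  mp <- nrow(E_plus); mm <- nrow(E_minus)
  if (min(mp, mm) < n_eig)
    stop("reduced space smaller than the number of requested roots")
  G <- matrix(0, mp + mm, mp + mm)
  G[seq_len(mp), seq_len(mp)] <- (E_plus + t(E_plus)) / 2
  G[mp + seq_len(mm), mp + seq_len(mm)] <- (E_minus + t(E_minus)) / 2
  M2 <- matrix(0, mp + mm, mp + mm)
  M2[seq_len(mp), mp + seq_len(mm)] <- S
  M2[mp + seq_len(mm), seq_len(mp)] <- t(S)
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (!is.null(counter)) counter$chol_2m <- counter$chol_2m + 1L
  if (is.null(R))
    solver_error("linresp_breakdown", "reduced metric diag(E+, E-) not positive definite")
  Ri <- backsolve(R, diag(mp + mm))
  B <- crossprod(Ri, M2) %*% Ri
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  if (!is.null(counter)) counter$ev_2m <- counter$ev_2m + 1L
  mu <- es$values[seq_len(n_eig)]          # largest 1/omega
  if (any(mu <= 0))
    solver_error("linresp_instability",
                 "nonpositive reduced eigenvalue in the Olsen reduced problem")
  u <- Ri %*% es$vectors[, seq_len(n_eig), drop = FALSE]
  list(omegas = 1 / mu,
       u_plus = u[seq_len(mp), , drop = FALSE],
       u_minus = u[mp + seq_len(mm), , drop = FALSE])
}

olsen_expand <- function(state, cand, problem, cfg, counter) {
  pu_p <- purify_candidates(state$Vp, cand$plus, images = NULL,
                            cfg = cfg, counter = counter)
  pu_m <- purify_candidates(state$Vm, cand$minus, images = NULL,
                            cfg = cfg, counter = counter)
  Wp <- pu_p$W; Wm <- pu_m$W
  added <- c(ncol(Wp), ncol(Wm))
  if (all(added == 0L)) return(list(state = state, added = added))

  if (ncol(Wp) > 0L) {
    LWp <- apply_op(problem, "ApB", Wp)
    BWp <- if (problem$is_tddft) Wp else apply_op(problem, "SpD", Wp)
    state$Ep <- rbind(cbind(state$Ep, crossprod(state$Vp, LWp)),
                      cbind(crossprod(Wp, state$LVp), crossprod(Wp, LWp)))
    state$Ep <- (state$Ep + t(state$Ep)) / 2
  }
  if (ncol(Wm) > 0L) {
    LWm <- apply_op(problem, "AmB", Wm)
    BWm <- if (problem$is_tddft) Wm else apply_op(problem, "SmD", Wm)
    state$Em <- rbind(cbind(state$Em, crossprod(state$Vm, LWm)),
                      cbind(crossprod(Wm, state$LVm), crossprod(Wm, LWm)))
    state$Em <- (state$Em + t(state$Em)) / 2
  }
  S <- state$S
  if (ncol(Wm) > 0L) S <- cbind(S, crossprod(state$Vp, BWm))
  if (ncol(Wp) > 0L) {
    right <- if (ncol(Wm) > 0L) cbind(state$BVm, BWm) else state$BVm
    S <- rbind(S, crossprod(Wp, right))
  }
  if (ncol(Wp) > 0L) {
    state$Vp <- cbind(state$Vp, Wp); state$LVp <- cbind(state$LVp, LWp)
    state$BVp <- cbind(state$BVp, BWp)
  }
  if (ncol(Wm) > 0L) {
    state$Vm <- cbind(state$Vm, Wm); state$LVm <- cbind(state$LVm, LWm)
    state$BVm <- cbind(state$BVm, BWm)
  }
  state$S <- S
  list(state = state, added = added)
}

olsen_restart <- function(state, u_plus, u_minus, cfg, counter) {
  collapse <- function(V, LV, BV, U) {
    eo <- euclid_orthonormalize_with(V %*% U, list(LX = LV %*% U, BX = BV %*% U),
                                     cfg, counter)
    list(V = eo$W, LV = eo$LX, BV = eo$BX)
  }
  p <- collapse(state$Vp, state$LVp, state$BVp, u_plus)
  m <- collapse(state$Vm, state$LVm, state$BVm, u_minus)
  state$Vp <- p$V; state$LVp <- p$LV; state$BVp <- p$BV
  state$Vm <- m$V; state$LVm <- m$LV; state$BVm <- m$BV
  state$Ep <- (crossprod(state$Vp, state$LVp) + t(crossprod(state$Vp, state$LVp))) / 2
  state$Em <- (crossprod(state$Vm, state$LVm) + t(crossprod(state$Vm, state$LVm))) / 2
  state$S <- crossprod(state$Vp, state$BVm)
  state
}

#' Solve the response problem with the Olsen reduced-space algorithm
#'
#' Same outer Davidson loop as [smogd_solve()] (guess, locking, thick
#' restart, identical convergence conventions) but with
#' Euclidean-orthonormal expansion vectors, the 2m-sized generalized
#' reduced problem of [olsen_solve_reduced()], the standard-form residual
#' `R+ = LVp u+ - omega BVm u-`, `R- = LVm u- - omega BVp u+`, and the
#' diagonal preconditioner obtained from
#' \eqn{(D_\Lambda - \omega D_\Omega) b = -R}.  Started from the same
#' guess on the same problem it generates the same expansion subspaces as
#' SMO-GD, hence identical Ritz values at every iteration.
#'
#' @inheritParams smogd_solve
#' @return a `solve_report`.
#' @export
olsen_solve <- function(problem, config, guess = NULL) {
  n <- problem$n; n_eig <- config$n_eig
  if (2L * n_eig > n) stop("need n_eig * 2 <= n")
  cfg <- config$ortho
  counter <- new_counter()
  mvp_start <- mvp_counters(problem)
  if (is.null(guess))
    guess <- gen_guess(problem, n_eig, perturb = config$guess_perturb,
                       seed = config$seed)

  state <- c(new_subspace(n), list(Ep = matrix(0, 0, 0), Em = matrix(0, 0, 0)))
  ex <- olsen_expand(state, guess, problem, cfg, counter)
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
    red <- olsen_solve_reduced(state$Ep, state$Em, state$S, n_eig, counter)
    omg <- red$omegas

    ## unit coefficient norm in the Lambda-orthonormal sense: normalize by
    ## the reduced-metric norm so residuals match SMO-GD's exactly
    cs <- sqrt(colSums(red$u_plus * (state$Ep %*% red$u_plus)) +
               colSums(red$u_minus * (state$Em %*% red$u_minus)))
    uPn <- sweep(red$u_plus, 2, cs, `/`)
    uMn <- sweep(red$u_minus, 2, cs, `/`)
    Rp <- state$LVp %*% uPn - sweep(state$BVm %*% uMn, 2, omg, `*`)
    Rm <- state$LVm %*% uMn - sweep(state$BVp %*% uPn, 2, omg, `*`)
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
      ev_2m = snap$ev_2m - prev_snap$ev_2m,
      chol_2m = snap$chol_2m - prev_snap$chol_2m,
      chol_small = snap$chol_small - prev_snap$chol_small)
    prev_snap <- snap; prev_mvp <- mvp_now

    if (all(converged)) { status <- "converged"; break }
    if (iter == config$max_iter) break

    active <- which(!converged)
    omga <- omg[active]
    a <- matrix(problem$diag_A, n, length(active))
    c_ <- -outer(problem$diag_Sigma, omga)
    b <- precond_2x2(a, c_, Rp[, active, drop = FALSE],
                     Rm[, active, drop = FALSE], config$precond_floor)
    cand <- parity_block(b$plus, b$minus)
    if (ncol(state$Vp) + length(active) > cap ||
        ncol(state$Vm) + length(active) > cap)
      state <- olsen_restart(state, red$u_plus, red$u_minus, cfg, counter)
    ex <- olsen_expand(state, cand, problem, cfg, counter)
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
  make_report("olsen", problem, config, red$omegas, converged, vecs,
              nrow(ritz_hist), status, ritz_hist, rms_hist, max_hist,
              do.call(rbind, iter_log), counter, mvp_start, mvp_guess)
}
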