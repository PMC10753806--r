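# ---------------------------------------------------------------------------
# Strattmann-Scuseria-Frisch (SSF) solver for the TD-DFT case
# (Sigma = I, Delta = 0).
#
# A single Euclidean-orthonormal subspace V carries both components; the
# projected problem E- E+ u+ = omega^2 u+ is non-Hermitian but is solved
# through the symmetric form
#     (E-)^{1/2} E+ (E-)^{1/2} u' = omega^2 u',   u+ = (E-)^{1/2} u'.
# Per iteration: 2 m-sized symmetric diagonalizations and 5 m-sized
# matrix-matrix multiplications; each root contributes two preconditioned
# residuals (right and left), so SSF performs twice as many operator
# applications per iteration as SMO-GD.
# ---------------------------------------------------------------------------

ssf_reduced <- function(Ep, Em, n_eig, counter) {
  es <- eigen(Em, symmetric = TRUE)
  counter$ev_m <- counter$ev_m + 1L
  if (any(es$values <= 0))
    solver_error("linresp_breakdown",
                 "SSF breakdown: reduced block E- not positive definite")
  Shalf <- es$vectors %*% (sqrt(es$values) * t(es$vectors))
  counter$mm_m <- counter$mm_m + 1L
  mid <- Shalf %*% Ep %*% Shalf
  counter$mm_m <- counter$mm_m + 2L
  em <- eigen((mid + t(mid)) / 2, symmetric = TRUE)
  counter$ev_m <- counter$ev_m + 1L
  m <- nrow(Ep)
  w2 <- em$values[seq(m, m - n_eig + 1L)]          # smallest omega^2
  if (any(w2 <= 0))
    solver_error("linresp_instability",
                 "nonpositive omega^2 in the SSF reduced problem")
  omegas <- sqrt(w2)
  uprime <- em$vectors[, seq(m, m - n_eig + 1L), drop = FALSE]
  u_plus <- Shalf %*% uprime
  counter$mm_m <- counter$mm_m + 1L
  u_minus <- sweep(Ep %*% u_plus, 2, omegas, `/`)  # from E+ u+ = omega u-
  counter$mm_m <- counter$mm_m + 1L
  ## biorthonormalize the left/right sets: u-_i' u+_j = omega_i delta_ij
  ## already holds, so one scaling per root suffices
  sc <- 1 / sqrt(omegas)
  list(omegas = omegas,
       u_plus = sweep(u_plus, 2, sc, `*`),
       u_minus = sweep(u_minus, 2, sc, `*`))
}

#' Solve a TD-DFT response problem with the SSF algorithm
#'
#' Davidson iteration on a single Euclidean-orthonormal subspace holding
#' both the symmetric and antisymmetric components (a nonfaithful
#' subspace representation that becomes exact at convergence).  Requires
#' `Sigma = I`, `Delta = 0` (`is_tddft` problems).  Convergence
#' conventions match [smogd_solve()].  The reduced solve diagonalizes
#' `E-`, forms its square root, symmetrizes `E+` with it and diagonalizes
#' again; breakdown of the `E-` factorization (possible for barely
#' diagonally dominant problems and near convergence) raises a
#' `linresp_breakdown` error.
#'
#' @inheritParams smogd_solve
#' @return a `solve_report`.
#' @export
ssf_solve <- function(problem, config, guess = NULL) {
  if (!problem$is_tddft)
    stop("the SSF algorithm applies only to TD-DFT problems (Sigma = I, Delta = 0)")
  n <- problem$n; n_eig <- config$n_eig
  if (2L * n_eig > n) stop("need n_eig * 2 <= n")
  cfg <- config$ortho
  counter <- new_counter()
  mvp_start <- mvp_counters(problem)
  if (is.null(guess))
    guess <- gen_guess(problem, n_eig, perturb = config$guess_perturb,
                       seed = config$seed)

  ## single subspace: start from the union of the guess components
  W0 <- cbind(guess$plus, guess$minus)
  pu <- purify_candidates(NULL, W0, cfg = cfg, counter = counter)
  V <- pu$W
  if (ncol(V) < n_eig)
    stop("start guess is rank-deficient: fewer independent vectors than roots")
  LVp <- apply_op(problem, "ApB", V)
  LVm <- apply_op(problem, "AmB", V)
  Ep <- (crossprod(V, LVp) + t(crossprod(V, LVp))) / 2
  Em <- (crossprod(V, LVm) + t(crossprod(V, LVm))) / 2
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
    red <- ssf_reduced(Ep, Em, n_eig, counter)
    omg <- red$omegas

    cs <- sqrt(colSums(red$u_plus * (Ep %*% red$u_plus)) +
               colSums(red$u_minus * (Em %*% red$u_minus)))
    uPn <- sweep(red$u_plus, 2, cs, `/`)
    uMn <- sweep(red$u_minus, 2, cs, `/`)
    Rp <- LVp %*% uPn - sweep(V %*% uMn, 2, omg, `*`)
    Rm <- LVm %*% uMn - sweep(V %*% uPn, 2, omg, `*`)
    nr <- residual_norms(Rp, Rm, n)
    converged <- nr$rms < config$tol_rms & nr$maxabs < config$tol_max

    ritz_hist <- rbind(ritz_hist, omg)
    rms_hist <- rbind(rms_hist, nr$rms)
    max_hist <- rbind(max_hist, nr$maxabs)
    snap <- counter_snapshot(counter); mvp_now <- mvp_counters(problem)
    iter_log[[iter]] <- data.frame(
      iter = iter, m = ncol(V), n_converged = sum(converged),
      mvp_batches = mvp_now$mvp_batches - prev_mvp$mvp_batches,
      mvp_cols = mvp_now$mvp_cols - prev_mvp$mvp_cols,
      ev_m = snap$ev_m - prev_snap$ev_m,
      mm_m = snap$mm_m - prev_snap$mm_m,
      chol_small = snap$chol_small - prev_snap$chol_small)
    prev_snap <- snap; prev_mvp <- mvp_now

    if (all(converged)) { status <- "converged"; break }
    if (iter == config$max_iter) break

    active <- which(!converged)
    omga <- omg[active]
    a <- matrix(problem$diag_A, n, length(active))
    c_ <- matrix(rep(-omga, each = n), n)
    b <- precond_2x2(a, c_, Rp[, active, drop = FALSE],
                     Rm[, active, drop = FALSE], config$precond_floor)
    cand <- cbind(b$plus, b$minus)        # two directions per root

    if (ncol(V) + ncol(cand) > cap) {
      X <- cbind(V %*% red$u_plus, V %*% red$u_minus)
      eo <- euclid_orthonormalize_with(X, list(LXp = cbind(LVp %*% red$u_plus,
                                                           LVp %*% red$u_minus),
                                               LXm = cbind(LVm %*% red$u_plus,
                                                           LVm %*% red$u_minus)),
                                       cfg, counter)
      V <- eo$W; LVp <- eo$LXp; LVm <- eo$LXm
      Ep <- (crossprod(V, LVp) + t(crossprod(V, LVp))) / 2
      Em <- (crossprod(V, LVm) + t(crossprod(V, LVm))) / 2
    }
    pu <- purify_candidates(V, cand, cfg = cfg, counter = counter)
    W <- pu$W
    if (ncol(W) == 0L)
      solver_error("linresp_stagnation",
                   "stagnation: all candidate directions linearly dependent and no root converged")
    LWp <- apply_op(problem, "ApB", W)
    LWm <- apply_op(problem, "AmB", W)
    Ep <- rbind(cbind(Ep, crossprod(V, LWp)),
                cbind(crossprod(W, LVp), crossprod(W, LWp)))
    Ep <- (Ep + t(Ep)) / 2
    Em <- rbind(cbind(Em, crossprod(V, LWm)),
                cbind(crossprod(W, LVm), crossprod(W, LWm)))
    Em <- (Em + t(Em)) / 2
    V <- cbind(V, W); LVp <- cbind(LVp, LWp); LVm <- cbind(LVm, LWm)
  }

  xP <- V %*% red$u_plus
  xM <- V %*% red$u_minus
  q <- 4 * colSums(xP * xM)               # x' Omega x for Sigma = I, Delta = 0
  vecs <- assemble_vectors(xP, xM, q)
  rownames(ritz_hist) <- rownames(rms_hist) <- rownames(max_hist) <- NULL
  make_report("ssf", problem, config, red$omegas, converged, vecs,
              nrow(ritz_hist), status, ritz_hist, rms_hist, max_hist,
              do.call(rbind, iter_log), counter, mvp_start, mvp_guess)
}
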