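# ---------------------------------------------------------------------------
# Dense full-space reference solver.  Exploits the same observation as
# SMO-GD: under ground-state stability Lambda is SPD, so the swapped form
# Omega x = (1/omega) Lambda x is symmetric-definite and can be solved
# with a Cholesky factorization plus one symmetric diagonalization.
# ---------------------------------------------------------------------------

#' Dense reference solution of the response problem
#'
#' Assembles the full \eqn{2n \times 2n} pencil, factors
#' \eqn{\Lambda = U^T U}, solves the standard symmetric eigenproblem
#' \eqn{U^{-T} \Omega U^{-1} w = (1/\omega) w} and returns the `n_eig`
#' smallest positive excitation energies with back-transformed
#' eigenvectors.  The spectrum's \eqn{\pm\omega} pairing is validated as a
#' side assertion.  A slower nonsymmetric pencil route
#' (`method = "pencil"`, eigendecomposition of \eqn{\Lambda^{-1}\Omega})
#' is kept as an independent cross-check.
#'
#' @param problem a dense-backed [response_problem()] with `n <= 5000`.
#' @param n_eig number of positive eigenvalues to return.
#' @param method `"cholesky"` (default) or `"pencil"`.
#' @return list with `omegas` (ascending, positive), `vectors`
#'   (`2n x n_eig`, columns scaled to unit Euclidean norm), and
#'   `all_mu` (the full spectrum of \eqn{1/\omega} values).
#' @export
dense_response_eig <- function(problem, n_eig, method = c("cholesky", "pencil")) {
  method <- match.arg(method)
  fo <- full_lambda_omega(problem)
  n2 <- nrow(fo$Lambda)
  if (n_eig < 1L || n_eig > problem$n) stop("need 1 <= n_eig <= n")

  if (method == "cholesky") {
    U <- tryCatch(chol(fo$Lambda), error = function(e) NULL)
    if (is.null(U))
      solver_error("linresp_instability",
                   "response matrix Lambda not positive definite: unstable ground state")
    Ui <- backsolve(U, diag(n2))
    M <- crossprod(Ui, fo$Omega) %*% Ui
    es <- eigen((M + t(M)) / 2, symmetric = TRUE)
    mu <- es$values
    W <- es$vectors
  } else {
    es <- eigen(solve(fo$Lambda, fo$Omega))
    if (max(abs(Im(es$values))) > 1e-8 * max(abs(es$values)))
      warning("pencil route returned markedly complex eigenvalues")
    ord <- order(Re(es$values), decreasing = TRUE)
    mu <- Re(es$values)[ord]
    W <- Re(es$vectors)[, ord, drop = FALSE]
  }

  ## pairing check: the mu spectrum must be symmetric about zero
  sym_err <- max(abs(sort(mu) + rev(sort(mu))))
  if (sym_err > 1e-8 * max(abs(mu)))
    warning(sprintf("eigenvalue pairing violated beyond tolerance (%.3g)", sym_err))

  pos <- which(mu > 0)
  if (length(pos) < n_eig)
    solver_error("linresp_instability", "fewer positive eigenvalues than requested")
  sel <- pos[seq_len(n_eig)]              # largest mu = smallest omega first
  omegas <- 1 / mu[sel]
  X <- if (method == "cholesky") Ui %*% W[, sel, drop = FALSE]
       else W[, sel, drop = FALSE]
  X <- sweep(X, 2, sqrt(colSums(X^2)), `/`)
  list(omegas = omegas, vectors = X, all_mu = mu)
}

#' Half-size TD-DFT reference spectrum
#'
#' Independent closed-form route for the TD-DFT case: the squared
#' excitation energies are the eigenvalues of
#' \eqn{(A-B)^{1/2} (A+B) (A-B)^{1/2}}.
#'
#' @param problem a dense-backed TD-DFT [response_problem()].
#' @param n_eig number of roots.
#' @return ascending excitation energies.
#' @export
tddft_halfsize_eig <- function(problem, n_eig) {
  if (!problem$is_tddft) stop("half-size route requires a TD-DFT problem")
  d <- problem$dense
  em <- eigen((d$AmB + t(d$AmB)) / 2, symmetric = TRUE)
  if (any(em$values <= 0))
    solver_error("linresp_instability", "A - B not positive definite")
  half <- em$vectors %*% (sqrt(em$values) * t(em$vectors))
  M <- half %*% d$ApB %*% half
  w2 <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sqrt(rev(w2)[seq_len(n_eig)])
}
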