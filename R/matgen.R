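# ---------------------------------------------------------------------------
# Structured random problem generator.
#
# The generator emulates the statistical structure of linear-response
# matrices: A+B and A-B are diagonally dominant SPD matrices with an
# increasing diagonal (excitation energies grow roughly linearly with the
# orbital-difference index), Sigma is a Gram matrix G G'/n and Delta a
# scaled antisymmetric part of a second random matrix.
# ---------------------------------------------------------------------------

## Derive independent sub-seeds from one master seed, kept below 2^31.
spawn_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

#' Generate a diagonally dominant SPD pair (A+B, A-B)
#'
#' Each matrix has off-diagonal entries drawn uniformly on \[0, 0.01\] and
#' symmetrised, and diagonal entry \eqn{1 + (i-1)/n + \mathrm{shift}} for
#' row \eqn{i}: a strongly diagonally dominant, strictly positive-definite
#' matrix whose diagonal increases linearly from 1 to about 2, mimicking a
#' well-conditioned orbital-Hessian spectrum.  The two matrices are drawn
#' independently; `A` and `B` are recoverable as half-sum and
#' half-difference.
#'
#' @param n matrix dimension (`n >= 1`).
#' @param seed integer master seed; the same `(n, seed)` always yields
#'   bit-identical matrices.
#' @param diag_shift nonnegative extra diagonal shift.
#' @return list with dense matrices `ApB` and `AmB`.
#' @export
gen_spd_pair <- function(n, seed = 1L, diag_shift = 0) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer")
  if (diag_shift < 0) stop("`diag_shift` must be nonnegative")
  seeds <- spawn_seeds(seed, 2L)
  one <- function(s) {
    M <- with_seed(s, matrix(runif(n * n, 0, 0.01), n, n))
    M <- (M + t(M)) / 2
    diag(M) <- 1 + (seq_len(n) - 1) / n + diag_shift
    M
  }
  list(ApB = one(seeds[1]), AmB = one(seeds[2]))
}

#' Generate metric blocks (Sigma, Delta)
#'
#' `Sigma = G G' / n` with `G` uniform on \[0,1) (a Gram matrix, hence
#' symmetric positive definite almost surely; the `1/n` scaling keeps its
#' conditioning moderate) and `Delta = delta_scale * (G' - G'^T)`, exactly
#' antisymmetric.  The default `delta_scale = 0.01` keeps the full metric
#' well behaved at the problem sizes used here.
#'
#' @param n matrix dimension.
#' @param seed integer master seed.
#' @param delta_scale scale applied to the antisymmetric block.
#' @return list with dense matrices `Sigma` and `Delta`.
#' @export
gen_metric <- function(n, seed = 1L, delta_scale = 0.01) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer")
  seeds <- spawn_seeds(seed, 2L)
  G <- with_seed(seeds[1], matrix(runif(n * n), n, n))
  Gp <- with_seed(seeds[2], matrix(runif(n * n), n, n))
  list(Sigma = tcrossprod(G) / n, Delta = delta_scale * (Gp - t(Gp)))
}

#' Generate a complete synthetic response problem
#'
#' Three problem families are provided:
#' \describe{
#'   \item{`"mcscf"`}{[gen_spd_pair()] response blocks with the general
#'     metric of [gen_metric()] (`Sigma` SPD, `Delta` antisymmetric).}
#'   \item{`"tddft"`}{the same response blocks with `Sigma = I`,
#'     `Delta = 0` (Hartree-Fock / TD-DFT case).}
#'   \item{`"stress"`}{fully random dense symmetric `A+B`, `A-B` (uniform
#'     \[0,1) entries, symmetrised) whose diagonals are shifted just enough
#'     that the smallest eigenvalue is 0.1: barely diagonally dominant
#'     problems that stress solver robustness; metric as in TD-DFT.}
#' }
#'
#' @param n problem half-dimension.
#' @param seed integer master seed.
#' @param kind one of `"mcscf"`, `"tddft"`, `"stress"`.
#' @param delta_scale passed to [gen_metric()] for `"mcscf"`.
#' @param check run operator contract checks on construction.
#' @return a dense-backed [response_problem()].
#' @export
gen_problem <- function(n, seed = 1L, kind = c("tddft", "mcscf", "stress"),
                        delta_scale = 0.01, check = TRUE) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  seeds <- spawn_seeds(seed, 3L)
  if (kind == "stress") {
    stress_one <- function(s) {
      M <- with_seed(s, matrix(runif(n * n), n, n))
      M <- (M + t(M)) / 2
      lam_min <- if (n == 1L) M[1, 1] else min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
      if (lam_min < 0.1) diag(M) <- diag(M) + (0.1 - lam_min)
      M
    }
    return(dense_response_problem(stress_one(seeds[1]), stress_one(seeds[2]),
                                  check = check))
  }
  pair <- gen_spd_pair(n, seeds[1])
  if (kind == "tddft")
    return(dense_response_problem(pair$ApB, pair$AmB, check = check))
  met <- gen_metric(n, seeds[2], delta_scale = delta_scale)
  dense_response_problem(pair$ApB, pair$AmB, met$Sigma, met$Delta, check = check)
}

#' Build the canonical start guess
#'
#' Returns `n_eig` guess vectors: the canonical basis vectors at the
#' `n_eig` smallest entries of `diag(A)` (ties broken toward the lower
#' index), with identical symmetric and antisymmetric components
#' \eqn{v^+ = v^-}.  When `perturb > 0`, each guess vector is perturbed by
#' adding one seeded uniform noise vector on \[0, perturb\] to both
#' components (the paired components stay equal, so every solver starts
#' from the same full-space guess).
#'
#' @param problem a [response_problem()].
#' @param n_eig number of guess vectors (`<= n`).
#' @param perturb noise amplitude; `0.01` reproduces the perturbed-guess
#'   protocol used in the convergence experiments, `0` gives the clean
#'   canonical guess.
#' @param seed seed for the noise.
#' @return a [parity_block()] with `n_eig` columns per component.
#' @export
gen_guess <- function(problem, n_eig, perturb = 0, seed = 1L) {
  n <- problem$n
  n_eig <- as.integer(n_eig)
  if (n_eig < 1L || n_eig > n) stop("`n_eig` must satisfy 1 <= n_eig <= n")
  idx <- order(problem$diag_A)[seq_len(n_eig)]   # stable: ties -> lower index
  V <- matrix(0, n, n_eig)
  V[cbind(idx, seq_len(n_eig))] <- 1
  if (perturb > 0) {
    noise <- with_seed(seed, matrix(runif(n * n_eig, 0, perturb), n, n_eig))
    V <- V + noise
  }
  parity_block(V, V)
}
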