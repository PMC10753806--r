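#' @importFrom stats runif rnorm
#' @importFrom methods as is
NULL

## Evaluate an expression under a temporary RNG seed, restoring the caller's
## RNG state afterwards.  All internal randomness goes through this helper so
## that library calls never disturb user-level reproducibility.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

as_col_matrix <- function(x, n) {
  if (is.null(dim(x))) x <- matrix(x, nrow = n)
  storage.mode(x) <- "double"
  x
}

#' Define a linear-response eigenvalue problem
#'
#' A response problem is the pencil \eqn{\Lambda x = \omega \Omega x} with
#' \deqn{\Lambda = \begin{pmatrix} A & B \\ B & A \end{pmatrix}, \qquad
#'       \Omega  = \begin{pmatrix} \Sigma & \Delta \\ -\Delta & -\Sigma \end{pmatrix},}
#' where \eqn{A}, \eqn{B}, \eqn{\Sigma} are symmetric \eqn{n \times n}
#' matrices, \eqn{\Delta} is antisymmetric, and \eqn{A+B}, \eqn{A-B},
#' \eqn{\Sigma} are positive definite (ground-state stability).  The
#' solvers never touch \eqn{A}, \eqn{B}, \eqn{\Sigma}, \eqn{\Delta}
#' directly: all they need are the four operator actions
#' \eqn{(A+B)v}, \eqn{(A-B)v}, \eqn{(\Sigma+\Delta)v}, \eqn{(\Sigma-\Delta)v}
#' plus the diagonals of \eqn{A} and \eqn{\Sigma} for preconditioning, so
#' matrix-free operators are supported on the same footing as dense ones.
#'
#' All four actions are column-batched: they accept an \eqn{n \times k}
#' matrix and return the operator applied to each column, so solvers can
#' expand several eigenvectors with a single application.
#'
#' On construction the operator contract is verified on a few random probe
#' vectors (fixed internal seed): \eqn{A \pm B} must be self-adjoint and
#' \eqn{\Sigma+\Delta} must be the adjoint of \eqn{\Sigma-\Delta}.
#'
#' @param n problem half-dimension (the blocks are \eqn{n \times n}).
#' @param apply_ApB,apply_AmB functions mapping an `n x k` matrix `V` to
#'   `(A+B) V` and `(A-B) V`.
#' @param apply_SpD,apply_SmD actions of `Sigma+Delta` and `Sigma-Delta`;
#'   default to the identity when `is_tddft` is `TRUE`.
#' @param diag_A,diag_Sigma length-`n` diagonals of `A` and `Sigma` used by
#'   the diagonal preconditioners; `diag_Sigma` defaults to ones for
#'   TD-DFT problems.
#' @param is_tddft logical; `TRUE` when `Sigma` is the identity and `Delta`
#'   is zero (Hartree-Fock / TD-DFT case).  Solvers then skip the metric
#'   products entirely.
#' @param dense optional list with dense matrices `ApB`, `AmB`, `Sigma`,
#'   `Delta` backing the operators; required by [full_lambda_omega()] and
#'   [dense_response_eig()].
#' @param check run the adjoint-consistency probe checks (default `TRUE`).
#' @return an object of class `response_problem`.
#' @seealso [dense_response_problem()], [gen_problem()], [apply_lambda()]
#' @export
response_problem <- function(n, apply_ApB, apply_AmB,
                             apply_SpD = NULL, apply_SmD = NULL,
                             diag_A, diag_Sigma = NULL,
                             is_tddft = FALSE, dense = NULL, check = TRUE) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("`n` must be a positive integer")
  if (is_tddft) {
    if (is.null(apply_SpD)) apply_SpD <- function(V) V
    if (is.null(apply_SmD)) apply_SmD <- function(V) V
    if (is.null(diag_Sigma)) diag_Sigma <- rep(1, n)
  }
  if (is.null(apply_SpD) || is.null(apply_SmD))
    stop("metric actions `apply_SpD`/`apply_SmD` are required unless `is_tddft`")
  if (length(diag_A) != n) stop("`diag_A` must have length n")
  if (length(diag_Sigma) != n) stop("`diag_Sigma` must have length n")

  counters <- new.env(parent = emptyenv())
  counters$mvp_batches <- 0L
  counters$mvp_cols <- 0L

  prob <- structure(list(
    n = n,
    apply_ApB = apply_ApB, apply_AmB = apply_AmB,
    apply_SpD = apply_SpD, apply_SmD = apply_SmD,
    diag_A = as.double(diag_A), diag_Sigma = as.double(diag_Sigma),
    is_tddft = isTRUE(is_tddft),
    dense = dense,
    counters = counters
  ), class = "response_problem")

  if (check) check_problem_adjoints(prob)
  prob
}

## Adjoint-consistency probes (3 random vectors, fixed internal seed).
check_problem_adjoints <- function(prob, n_probe = 3L, tol = 1e-12) {
  n <- prob$n
  with_seed(760451L, {
    V <- matrix(runif(n * n_probe, -1, 1), n)
    W <- matrix(runif(n * n_probe, -1, 1), n)
  })
  scale <- outer(sqrt(colSums(V^2)), sqrt(colSums(W^2)))
  sym_p <- abs(crossprod(W, prob$apply_ApB(V)) - t(crossprod(V, prob$apply_ApB(W))))
  sym_m <- abs(crossprod(W, prob$apply_AmB(V)) - t(crossprod(V, prob$apply_AmB(W))))
  if (max(sym_p / scale) > tol || max(sym_m / scale) > tol)
    stop("operator contract violated: A+B or A-B is not self-adjoint on random probes")
  adj <- abs(crossprod(W, prob$apply_SpD(V)) - t(crossprod(V, prob$apply_SmD(W))))
  if (max(adj / scale) > tol)
    stop("operator contract violated: Sigma+Delta is not the adjoint of Sigma-Delta")
  invisible(prob)
}

#' @export
print.response_problem <- function(x, ...) {
  cat(sprintf("<response_problem> n = %d, %s, %s\n", x$n,
              if (x$is_tddft) "TD-DFT metric (Sigma = I, Delta = 0)" else "general metric",
              if (is.null(x$dense)) "matrix-free" else "dense-backed"))
  invisible(x)
}

#' Build a response problem from dense matrices
#'
#' Convenience constructor wrapping dense symmetric `A+B`, `A-B` and metric
#' blocks `Sigma` (symmetric positive definite) and `Delta` (antisymmetric)
#' into column-batched operator closures.  The dense matrices are retained
#' so that [full_lambda_omega()] and the dense reference solver can use
#' them.
#'
#' @param ApB,AmB dense symmetric positive-definite `n x n` matrices.
#' @param Sigma,Delta dense metric blocks; both `NULL` for TD-DFT
#'   (`Sigma = I`, `Delta = 0`).
#' @param check verify operator adjointness on random probes.
#' @return a [response_problem()].
#' @export
dense_response_problem <- function(ApB, AmB, Sigma = NULL, Delta = NULL,
                                   check = TRUE) {
  ApB <- as.matrix(ApB); AmB <- as.matrix(AmB)
  n <- nrow(ApB)
  if (!all(dim(ApB) == n) || !all(dim(AmB) == n))
    stop("`ApB` and `AmB` must be square and of equal size")
  is_tddft <- is.null(Sigma) && is.null(Delta)
  if (is_tddft) {
    Sigma <- diag(n); Delta <- matrix(0, n, n)
  } else {
    if (is.null(Sigma)) Sigma <- diag(n)
    if (is.null(Delta)) Delta <- matrix(0, n, n)
    Sigma <- as.matrix(Sigma); Delta <- as.matrix(Delta)
  }
  SpD <- Sigma + Delta
  SmD <- Sigma - Delta
  response_problem(
    n = n,
    apply_ApB = function(V) ApB %*% V,
    apply_AmB = function(V) AmB %*% V,
    apply_SpD = if (is_tddft) function(V) V else function(V) SpD %*% V,
    apply_SmD = if (is_tddft) function(V) V else function(V) SmD %*% V,
    diag_A = (diag(ApB) + diag(AmB)) / 2,
    diag_Sigma = diag(Sigma),
    is_tddft = is_tddft,
    dense = list(ApB = ApB, AmB = AmB, Sigma = Sigma, Delta = Delta),
    check = check
  )
}

## Counted operator application.  `which` is one of "ApB", "AmB", "SpD",
## "SmD".  Every solver MVP goes through here so that the instrumentation
## counters are trustworthy.
apply_op <- function(prob, which, V) {
  V <- as_col_matrix(V, prob$n)
  if (nrow(V) != prob$n) stop("dimension error: operand rows != n")
  prob$counters$mvp_batches <- prob$counters$mvp_batches + 1L
  prob$counters$mvp_cols <- prob$counters$mvp_cols + ncol(V)
  fn <- switch(which,
    ApB = prob$apply_ApB, AmB = prob$apply_AmB,
    SpD = prob$apply_SpD, SmD = prob$apply_SmD,
    stop("unknown operator tag: ", which))
  out <- fn(V)
  as_col_matrix(out, prob$n)
}

#' Reset or read a problem's matrix-vector-product counters
#'
#' Each call to one of the four operator actions on a block of `k` columns
#' counts as one batch and `k` columns.
#'
#' @param problem a [response_problem()].
#' @return `mvp_counters()` returns a list with `mvp_batches` and
#'   `mvp_cols`; `reset_mvp_counters()` zeroes them invisibly.
#' @export
mvp_counters <- function(problem) {
  list(mvp_batches = problem$counters$mvp_batches,
       mvp_cols = problem$counters$mvp_cols)
}

#' @rdname mvp_counters
#' @export
reset_mvp_counters <- function(problem) {
  problem$counters$mvp_batches <- 0L
  problem$counters$mvp_cols <- 0L
  invisible(problem)
}

# ---------------------------------------------------------------------------
# Parity (symmetric/antisymmetric) vector algebra
# ---------------------------------------------------------------------------

#' Paired symmetric/antisymmetric vector blocks
#'
#' Solutions of the response problem come in \eqn{\pm\omega} pairs, and the
#' solvers exploit this by expanding every eigenvector in symmetric vectors
#' \eqn{v^{(+)} = (v^+, v^+)} and antisymmetric vectors
#' \eqn{v^{(-)} = (v^-, -v^-)}.  A `parity_block` stores the half-size
#' components `plus` and `minus` (each `n x k`); the full
#' \eqn{2n}-dimensional vector is only ever materialised at I/O boundaries
#' via [parity_embed()], with top half \eqn{v^+ + v^-} and bottom half
#' \eqn{v^+ - v^-}.
#'
#' @param plus,minus `n x k` matrices (or length-`n` vectors) holding the
#'   symmetric and antisymmetric components.
#' @return an object of class `parity_block`.
#' @export
parity_block <- function(plus, minus) {
  if (is.null(dim(plus))) plus <- matrix(plus, ncol = 1)
  if (is.null(dim(minus))) minus <- matrix(minus, ncol = 1)
  if (!all(dim(plus) == dim(minus)))
    stop("dimension error: `plus` and `minus` must have identical shape")
  structure(list(plus = plus, minus = minus), class = "parity_block")
}

#' @export
print.parity_block <- function(x, ...) {
  cat(sprintf("<parity_block> n = %d, k = %d\n", nrow(x$plus), ncol(x$plus)))
  invisible(x)
}

#' @rdname parity_block
#' @param v a `parity_block`.
#' @export
parity_embed <- function(v) {
  stopifnot(inherits(v, "parity_block"))
  rbind(v$plus + v$minus, v$plus - v$minus)
}

#' @rdname parity_block
#' @param x a `2n x k` matrix of full-space vectors.
#' @export
parity_split <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n2 <- nrow(x)
  if (n2 %% 2L != 0L) stop("dimension error: full-space vectors must have even length")
  n <- n2 %/% 2L
  top <- x[seq_len(n), , drop = FALSE]
  bot <- x[n + seq_len(n), , drop = FALSE]
  parity_block((top + bot) / 2, (top - bot) / 2)
}

#' Apply the response matrix or the metric to a parity block
#'
#' The response matrix \eqn{\Lambda} preserves parity:
#' \eqn{\Lambda v^{(+)}} is symmetric with component \eqn{(A+B)v^+} and
#' \eqn{\Lambda v^{(-)}} is antisymmetric with component \eqn{(A-B)v^-}.
#' The metric \eqn{\Omega} swaps parity: the symmetric component of
#' \eqn{\Omega v} is \eqn{(\Sigma-\Delta)v^-} and the antisymmetric one is
#' \eqn{(\Sigma+\Delta)v^+}.  This block structure is what lets the
#' reduced-space problem decouple.
#'
#' @param problem a [response_problem()].
#' @param v a [parity_block()] with `n` rows per component.
#' @return a [parity_block()].
#' @export
apply_lambda <- function(problem, v) {
  stopifnot(inherits(v, "parity_block"))
  if (nrow(v$plus) != problem$n) stop("dimension error: parity block rows != n")
  parity_block(apply_op(problem, "ApB", v$plus),
               apply_op(problem, "AmB", v$minus))
}

#' @rdname apply_lambda
#' @export
apply_omega <- function(problem, v) {
  stopifnot(inherits(v, "parity_block"))
  if (nrow(v$plus) != problem$n) stop("dimension error: parity block rows != n")
  parity_block(apply_op(problem, "SmD", v$minus),
               apply_op(problem, "SpD", v$plus))
}

#' Assemble the dense full-space response matrix and metric
#'
#' Materialises \eqn{\Lambda = [[A,B],[B,A]]} and
#' \eqn{\Omega = [[\Sigma,\Delta],[-\Delta,-\Sigma]]} as dense
#' \eqn{2n \times 2n} matrices.  Only available for dense-backed problems
#' and guarded to \eqn{n \le 5000}; intended for reference solutions and
#' testing, not production solves.
#'
#' @param problem a dense-backed [response_problem()].
#' @return list with components `Lambda` and `Omega`.
#' @export
full_lambda_omega <- function(problem) {
  if (is.null(problem$dense))
    stop("unsupported operation: problem has no dense backing")
  if (problem$n > 5000L)
    stop("dense assembly guarded to n <= 5000")
  d <- problem$dense
  A <- (d$ApB + d$AmB) / 2
  B <- (d$ApB - d$AmB) / 2
  Lambda <- rbind(cbind(A, B), cbind(B, A))
  Omega <- rbind(cbind(d$Sigma, d$Delta), cbind(-d$Delta, -d$Sigma))
  list(Lambda = Lambda, Omega = Omega)
}
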