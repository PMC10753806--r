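# ---------------------------------------------------------------------------
# Orthogonalization primitives: projection against an existing basis,
# Cholesky-based orthonormalization, and metric (Lambda-) orthonormalization.
# All of them act by right-multiplication with triangular factors, so
# orthogonality established earlier is preserved exactly in exact
# arithmetic.
# ---------------------------------------------------------------------------

#' Orthogonalization settings
#'
#' @param proj_threshold stop iterating projection/orthonormalization
#'   sweeps once the max-abs cross product with the existing basis is below
#'   this value.
#' @param max_sweeps maximum number of projection + Cholesky sweeps.
#' @param chol_retry_shift relative diagonal shift applied once when a
#'   Cholesky factorization of a near-singular overlap fails.
#' @param drop_tol candidate columns whose norm falls below
#'   `drop_tol` times their pre-projection norm are dropped as linearly
#'   dependent rather than orthonormalized.
#' @return a list of class `ortho_config`.
#' @export
ortho_config <- function(proj_threshold = 1e-12, max_sweeps = 4L,
                         chol_retry_shift = 1e-14, drop_tol = 1e-10) {
  stopifnot(proj_threshold > 0, chol_retry_shift > 0, max_sweeps >= 1L,
            drop_tol > 0)
  structure(list(proj_threshold = proj_threshold,
                 max_sweeps = as.integer(max_sweeps),
                 chol_retry_shift = chol_retry_shift,
                 drop_tol = drop_tol),
            class = "ortho_config")
}

#' Project a block out of the span of an orthonormal basis
#'
#' Computes `W - V (C' W)` where `C = V` for the Euclidean inner product or
#' `C = metric_images` (the stored products \eqn{\Lambda V}) when `V` is
#' orthonormal in the \eqn{\Lambda} inner product.  Using the stored images
#' makes the metric projection free of operator applications.
#'
#' @param V `n x m` basis block, orthonormal in the inner product in use;
#'   may have zero columns.
#' @param W `n x p` block to purify.
#' @param metric_images optional `n x m` block of metric images of `V`.
#' @return the projected `n x p` block.
#' @export
project_out <- function(V, W, metric_images = NULL) {
  if (is.null(dim(W))) W <- matrix(W, ncol = 1)
  if (is.null(V) || NCOL(V) == 0L) return(W)
  if (nrow(V) != nrow(W)) stop("dimension error: V and W row mismatch")
  C <- if (is.null(metric_images)) V else metric_images
  if (!all(dim(C) == dim(V))) stop("dimension error: metric_images shape")
  W - V %*% crossprod(C, W)
}

## One shifted-Cholesky orthonormalization pass.  Returns list(Q, ok):
## `ok = FALSE` means even the shifted overlap would not factor (or gave a
## non-finite result); callers then fall back to pivoted column dropping.
chol_pass <- function(W, cfg, counter = NULL) {
  p <- ncol(W)
  M <- crossprod(W)
  if (!is.null(counter)) counter$chol_small <- counter$chol_small + 1L
  R <- tryCatch(chol(M), error = function(e) NULL)
  shifted <- is.null(R)
  if (shifted) {
    Ms <- M + diag(cfg$chol_retry_shift * max(diag(M)), p)
    R <- tryCatch(chol(Ms), error = function(e) NULL)
  }
  if (is.null(R)) return(list(Q = W, ok = FALSE, shifted = TRUE))
  Q <- W %*% backsolve(R, diag(p))
  if (!all(is.finite(Q))) return(list(Q = W, ok = FALSE, shifted = shifted))
  list(Q = Q, ok = TRUE, shifted = shifted)
}

## Pivoted-Cholesky rank detection: indices of a numerically independent
## column subset (relative diagonal-decay cutoff).
independent_columns <- function(W) {
  if (ncol(W) == 0L) return(integer(0))
  M <- crossprod(W)
  piv <- suppressWarnings(chol(M, pivot = TRUE))
  r <- attr(piv, "rank")
  dR <- diag(piv)
  r <- min(r, sum(dR > .Machine$double.eps^0.45 * max(dR[1], 0)))
  if (r == 0L) return(integer(0))
  sort(attr(piv, "pivot")[seq_len(r)])
}

#' Cholesky-based orthonormalization
#'
#' Orthonormalizes the columns of `W` by factoring the overlap
#' `W'W = L L'` and right-multiplying by the inverse transposed factor.
#' The pass is repeated until the overlap is the identity to within
#' `proj_threshold` (two passes suffice in practice).
#'
#' @param W `n x p` block of numerically full column rank.
#' @param cfg an [ortho_config()].
#' @return `n x p` block with orthonormal columns.
#' @export
ortho_cd <- function(W, cfg = ortho_config()) {
  if (is.null(dim(W))) W <- matrix(W, ncol = 1)
  if (ncol(W) == 0L) return(W)
  W0 <- W
  err <- Inf
  bad <- FALSE
  for (sweep in seq_len(cfg$max_sweeps)) {
    cp <- chol_pass(W, cfg)
    ## a genuinely full-rank block factors without the rescue shift;
    ## needing it signals numerically dependent columns
    if (!cp$ok || cp$shifted) { bad <- TRUE; break }
    W <- cp$Q
    err <- max(abs(crossprod(W) - diag(ncol(W))))
    if (err < cfg$proj_threshold) break
  }
  if (bad || err > 1e-8) {
    r <- length(independent_columns(W0))
    stop(sprintf("rank-deficiency: overlap Cholesky failed for %d of %d columns",
                 ncol(W0) - r, ncol(W0)))
  }
  W
}

#' Metric (Lambda-) orthonormalization of a block with stored images
#'
#' Given a block `W` and its images `LW = Lambda W`, factors the metric
#' overlap `M = W' LW = L L'` and right-multiplies both `W` and `LW` (and
#' any blocks in `extra`) by the inverse transposed factor, producing a
#' block orthonormal in the \eqn{\Lambda} inner product without any new
#' operator applications.  For a single vector this reduces to division by
#' the \eqn{\Lambda}-norm, the scalar factor being the square root of `M`.
#'
#' @param W `n x p` block.
#' @param LW images `Lambda W`, same shape.
#' @param extra optional named list of same-shape blocks to co-transform.
#' @param cfg an [ortho_config()].
#' @param counter optional environment whose `chol_small` field is
#'   incremented per factorization.
#' @return list with elements `W`, `LW` and the transformed `extra` blocks.
#' @export
metric_orthonormalize <- function(W, LW, extra = NULL, cfg = ortho_config(),
                                  counter = NULL) {
  if (is.null(dim(W))) W <- matrix(W, ncol = 1)
  if (is.null(dim(LW))) LW <- matrix(LW, ncol = 1)
  if (!all(dim(W) == dim(LW))) stop("dimension error: W and LW shape mismatch")
  if (ncol(W) == 0L) return(c(list(W = W, LW = LW), extra))
  for (sweep in seq_len(cfg$max_sweeps)) {
    M <- crossprod(W, LW)
    M <- (M + t(M)) / 2
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) {
      Ms <- M + diag(cfg$chol_retry_shift * max(abs(diag(M))), ncol(M))
      R <- tryCatch(chol(Ms), error = function(e) NULL)
    }
    if (!is.null(counter)) counter$chol_small <- counter$chol_small + 1L
    if (is.null(R))
      stop("numerical breakdown: metric overlap not positive definite; ",
           "tighten the preceding orthogonalization")
    Ri <- backsolve(R, diag(ncol(W)))
    W <- W %*% Ri
    LW <- LW %*% Ri
    if (!is.null(extra)) extra <- lapply(extra, function(X) X %*% Ri)
    if (max(abs(crossprod(W, LW) - diag(ncol(W)))) < 1e-13) break
  }
  c(list(W = W, LW = LW), extra)
}

## The full "enlarge the subspace" purification used by the solvers:
## repeatedly project W out of span(V) (in the inner product defined by
## `images`: Euclidean when images is NULL, Lambda otherwise) and
## re-orthonormalize among the survivors with ortho_cd, until the cross
## product with V is below threshold.  Columns that lose almost all of
## their norm are dropped as linearly dependent.  Returns the purified
## block (possibly with fewer columns) plus the number of sweeps used.
purify_candidates <- function(V, W, images = NULL, cfg = ortho_config(),
                              counter = NULL) {
  if (is.null(dim(W))) W <- matrix(W, ncol = 1)
  norms0 <- sqrt(colSums(W^2))
  W <- W[, norms0 > 0, drop = FALSE]
  norms0 <- norms0[norms0 > 0]
  if (ncol(W) == 0L) return(list(W = W, sweeps = 0L))
  cross_of <- function(W) {
    if (is.null(V) || NCOL(V) == 0L || ncol(W) == 0L) return(0)
    C <- if (is.null(images)) V else images
    max(abs(crossprod(C, W)))
  }
  qual_of <- function(W) {
    if (ncol(W) == 0L) return(0)
    max(abs(crossprod(W) - diag(ncol(W))))
  }
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    W <- project_out(V, W, metric_images = images)
    nn <- sqrt(colSums(W^2))
    keep <- nn > cfg$drop_tol * norms0 & nn > 0
    W <- W[, keep, drop = FALSE]
    norms0 <- norms0[keep]
    if (ncol(W) == 0L) break
    cp <- chol_pass(W, cfg, counter = counter)
    if (!cp$ok || qual_of(cp$Q) > 0.5) {
      ## columns numerically dependent among themselves: keep an
      ## independent subset and re-orthonormalize it
      kept <- independent_columns(W)
      W <- W[, kept, drop = FALSE]
      norms0 <- norms0[kept]
      if (ncol(W) == 0L) break
      cp <- chol_pass(W, cfg, counter = counter)
      if (!cp$ok) { W <- W[, 0, drop = FALSE]; break }
    }
    W <- cp$Q
    norms0 <- rep(1, ncol(W))
    if ((cross_of(W) < cfg$proj_threshold && qual_of(W) < cfg$proj_threshold) ||
        sweeps >= cfg$max_sweeps) break
  }
  if (!is.null(counter)) counter$max_sweeps <- max(counter$max_sweeps, sweeps)
  list(W = W, sweeps = sweeps)
}
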