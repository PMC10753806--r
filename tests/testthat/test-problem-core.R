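test_that("full-space assembly reproduces the block structure", {
  p <- dense_response_problem(ApB = matrix(3), AmB = matrix(1))
  fo <- full_lambda_omega(p)
  expect_equal(fo$Lambda, rbind(c(2, 1), c(1, 2)))
  expect_equal(fo$Omega, rbind(c(1, 0), c(0, -1)))

  # symmetry is exact by construction
  p2 <- gen_problem(7, seed = 42, kind = "mcscf")
  fo2 <- full_lambda_omega(p2)
  expect_identical(max(abs(fo2$Lambda - t(fo2$Lambda))), 0)
  expect_identical(max(abs(fo2$Omega - t(fo2$Omega))), 0)
})

test_that("assembled blocks match an element-by-element loop oracle", {
  n <- 5
  A <- rand_sym(n, 1); B <- rand_sym(n, 2, scale = 0.3)
  Sigma <- rand_spd_cond(n, 3); set.seed(4)
  G <- matrix(runif(n * n), n); Delta <- 0.1 * (G - t(G))
  p <- dense_response_problem(A + B, A - B, Sigma, Delta)
  fo <- full_lambda_omega(p)
  L <- matrix(0, 2 * n, 2 * n); O <- matrix(0, 2 * n, 2 * n)
  for (i in 1:n) for (j in 1:n) {
    L[i, j] <- A[i, j];         L[i, n + j] <- B[i, j]
    L[n + i, j] <- B[i, j];     L[n + i, n + j] <- A[i, j]
    O[i, j] <- Sigma[i, j];     O[i, n + j] <- Delta[i, j]
    O[n + i, j] <- -Delta[i, j]; O[n + i, n + j] <- -Sigma[i, j]
  }
  expect_equal(fo$Lambda, L, tolerance = 1e-14)
  expect_equal(fo$Omega, O, tolerance = 1e-14)
})

test_that("matrix-free problems refuse dense assembly", {
  p <- response_problem(3, function(V) 2 * V, function(V) V,
                        diag_A = rep(1.5, 3), is_tddft = TRUE)
  expect_error(full_lambda_omega(p), "dense backing")
})

test_that("parity embedding round-trips to machine precision", {
  set.seed(9)
  v <- parity_block(matrix(rnorm(12), 4), matrix(rnorm(12), 4))
  w <- parity_split(parity_embed(v))
  expect_equal(w$plus, v$plus, tolerance = 1e-15)
  expect_equal(w$minus, v$minus, tolerance = 1e-15)
  # dyadic components round-trip bit-exactly
  v2 <- parity_block(matrix(c(1, 0.5, -0.25, 8)), matrix(c(2, -4, 0.125, 1)))
  w2 <- parity_split(parity_embed(v2))
  expect_identical(w2$plus, v2$plus)
  expect_identical(w2$minus, v2$minus)
})

test_that("Lambda preserves parity and Omega swaps it", {
  p <- gen_problem(6, seed = 5, kind = "mcscf")
  set.seed(6)
  v <- parity_block(matrix(rnorm(6)), matrix(0, 6, 1))
  lv <- apply_lambda(p, v)
  expect_identical(lv$minus, matrix(0, 6, 1))
  ov <- apply_omega(p, v)
  expect_equal(ov$plus, matrix(0, 6, 1))

  # TD-DFT identity metric: Omega just swaps the components
  pt <- gen_problem(6, seed = 5, kind = "tddft")
  w <- parity_block(matrix(rnorm(6)), matrix(rnorm(6)))
  ow <- apply_omega(pt, w)
  expect_identical(ow$plus, w$minus)
  expect_identical(ow$minus, w$plus)
})

test_that("parity application agrees with the dense full-space route", {
  p <- gen_problem(6, seed = 17, kind = "mcscf")
  fo <- full_lambda_omega(p)
  set.seed(18)
  v <- parity_block(matrix(rnorm(18), 6), matrix(rnorm(18), 6))
  lv_dense <- parity_split(fo$Lambda %*% parity_embed(v))
  lv <- apply_lambda(p, v)
  expect_equal(lv$plus, lv_dense$plus, tolerance = 1e-14)
  expect_equal(lv$minus, lv_dense$minus, tolerance = 1e-14)
  ov_dense <- parity_split(fo$Omega %*% parity_embed(v))
  ov <- apply_omega(p, v)
  expect_equal(ov$plus, ov_dense$plus, tolerance = 1e-14)
  expect_equal(ov$minus, ov_dense$minus, tolerance = 1e-14)
})

test_that("the full spectrum comes in positive-negative pairs", {
  for (kind in c("tddft", "mcscf")) {
    p <- gen_problem(20, seed = 23, kind = kind)
    mu <- dense_response_eig(p, 3)$all_mu
    expect_lt(max(abs(sort(mu) + rev(sort(mu)))), 1e-10 * max(abs(mu)))
  }
})

test_that("operator contract violations are caught at construction", {
  set.seed(31)
  M <- matrix(runif(25), 5)   # not symmetric
  expect_error(
    response_problem(5, function(V) M %*% V, function(V) V,
                     diag_A = diag(M), is_tddft = TRUE),
    "self-adjoint")
  # Sigma+Delta must be the adjoint of Sigma-Delta
  expect_error(
    response_problem(5, function(V) 2 * V, function(V) V,
                     apply_SpD = function(V) M %*% V,
                     apply_SmD = function(V) M %*% V,
                     diag_A = rep(2, 5), diag_Sigma = diag(M)),
    "adjoint")
})

test_that("mvp counters track batches and columns", {
  p <- gen_problem(8, seed = 2, kind = "tddft")
  reset_mvp_counters(p)
  invisible(apply_lambda(p, parity_block(matrix(1, 8, 3), matrix(1, 8, 3))))
  cnt <- mvp_counters(p)
  expect_identical(cnt$mvp_batches, 2L)
  expect_identical(cnt$mvp_cols, 6L)
})
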