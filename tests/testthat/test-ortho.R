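test_that("project_out handles the empty basis and is idempotent", {
  set.seed(1)
  W <- matrix(rnorm(20), 10)
  expect_identical(project_out(matrix(0, 10, 0), W), W)
  V <- ortho_cd(matrix(rnorm(30), 10))
  expect_lt(max(abs(project_out(V, V))), 1e-14)
})

test_that("metric projection annihilates Lambda cross-terms within two sweeps", {
  n <- 20
  Lam <- rand_spd_cond(n, 4, cond = 100)
  set.seed(5)
  V0 <- matrix(rnorm(n * 3), n)
  mo <- metric_orthonormalize(ortho_cd(V0), Lam %*% ortho_cd(V0))
  V <- mo$W; LV <- mo$LW
  W <- matrix(rnorm(n * 2), n)
  cnt <- new.env(); cnt$chol_small <- 0L; cnt$max_sweeps <- 0L
  pu <- linresp:::purify_candidates(V, W, images = LV, counter = cnt)
  expect_lte(cnt$max_sweeps, 2L)
  expect_lt(max(abs(crossprod(LV, pu$W))), 1e-12)
})

test_that("ortho_cd orthonormalizes, including ill-conditioned input", {
  set.seed(7)
  W <- matrix(rnorm(50), 10)
  Q0 <- ortho_cd(W)
  # fixed point: an orthonormal block passes through unchanged
  expect_equal(ortho_cd(Q0), Q0, tolerance = 1e-14)
  # exactly-identity overlap (canonical columns): bit-exact pass-through
  E <- diag(10)[, 1:3]
  expect_identical(ortho_cd(E), E)
  # single vector: plain normalization
  w <- matrix(rnorm(10))
  expect_equal(ortho_cd(w), w / sqrt(sum(w^2)), tolerance = 1e-15)
  # condition number ~1e8
  set.seed(8)
  U <- qr.Q(qr(matrix(rnorm(2500), 50)))[, 1:5]
  Wi <- U %*% diag(c(1, 1e-2, 1e-4, 1e-6, 1e-8)) %*%
    qr.Q(qr(matrix(rnorm(25), 5)))
  Qi <- ortho_cd(Wi)
  expect_lt(max(abs(crossprod(Qi) - diag(5))), 1e-13)
})

test_that("ortho_cd reports rank deficiency with the offending column count", {
  set.seed(9)
  w <- matrix(rnorm(10))
  expect_error(ortho_cd(cbind(w, w, 2 * w)), "2 of 3 columns")
})

test_that("metric_orthonormalize produces a Lambda-orthonormal block", {
  # p = 1: division by the Lambda-norm (scalar Cholesky = square root)
  n <- 12
  Lam <- rand_spd_cond(n, 11, cond = 50)
  set.seed(12)
  w <- matrix(rnorm(n))
  mo <- metric_orthonormalize(w, Lam %*% w)
  expect_equal(mo$W, w / sqrt(drop(crossprod(w, Lam %*% w))), tolerance = 1e-14)

  # Lambda = I degenerates to Euclidean orthonormalization
  W <- matrix(rnorm(n * 3), n)
  moI <- metric_orthonormalize(W, W)
  expect_equal(moI$W, ortho_cd(W), tolerance = 1e-12)

  # random SPD metric, explicit dense check, images co-transformed
  n <- 30
  Lam <- rand_spd_cond(n, 13, cond = 1000)
  set.seed(14)
  W <- matrix(rnorm(n * 4), n)
  mo <- metric_orthonormalize(W, Lam %*% W)
  expect_lt(max(abs(crossprod(mo$W, Lam %*% mo$W) - diag(4))), 1e-12)
  expect_equal(mo$LW, Lam %*% mo$W, tolerance = 1e-10)
})

test_that("the full enlargement sequence keeps the basis Lambda-orthonormal", {
  # composition contract: old block + purified/metric-orthonormalized new
  # block is Lambda-orthonormal across ALL columns
  n <- 40
  Lam <- rand_spd_cond(n, 21, cond = 100)
  set.seed(22)
  V0 <- ortho_cd(matrix(rnorm(n * 4), n))
  mo <- metric_orthonormalize(V0, Lam %*% V0)
  V <- mo$W; LV <- mo$LW
  cnt <- new.env(); cnt$chol_small <- 0L; cnt$max_sweeps <- 0L
  W <- matrix(rnorm(n * 3), n)
  pu <- linresp:::purify_candidates(V, W, images = LV, counter = cnt)
  mo2 <- metric_orthonormalize(pu$W, Lam %*% pu$W)
  Vall <- cbind(V, mo2$W)
  expect_lt(max(abs(crossprod(Vall, Lam %*% Vall) - diag(ncol(Vall)))), 1e-10)
})

test_that("linearly dependent candidates are dropped, not fatal", {
  n <- 15
  set.seed(23)
  V <- ortho_cd(matrix(rnorm(n * 3), n))
  inside <- V %*% matrix(rnorm(6), 3)      # entirely in span(V)
  fresh <- matrix(rnorm(n), n)
  pu <- linresp:::purify_candidates(V, cbind(inside, fresh))
  expect_identical(ncol(pu$W), 1L)
  expect_lt(max(abs(crossprod(V, pu$W))), 1e-12)
})
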