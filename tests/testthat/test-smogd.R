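test_that("solve_reduced recovers the half-size spectrum", {
  # scalar case: omega = 1/s, u- = omega * s * u+ = u+
  r1 <- solve_reduced(matrix(2), 1)
  expect_equal(r1$omegas, 0.5)
  expect_equal(abs(r1$u_plus), matrix(1))
  expect_equal(r1$u_minus, r1$u_plus)

  # diagonal case: omega = 1/s, sorted ascending
  rd <- solve_reduced(diag(c(2, 0.5)), 2)
  expect_equal(rd$omegas, c(0.5, 2))

  # random 6x6 against the dense 2m reduced-problem oracle
  set.seed(33)
  S <- matrix(rnorm(36), 6)
  red <- solve_reduced(S, 3)
  M2 <- rbind(cbind(matrix(0, 6, 6), S), cbind(t(S), matrix(0, 6, 6)))
  mu <- eigen(M2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(red$omegas, sort(1 / mu[1:3]), tolerance = 1e-12)
  # block relations S u- = (1/omega) u+ and S' u+ = (1/omega) u-
  expect_lt(max(abs(S %*% red$u_minus -
                    sweep(red$u_plus, 2, red$omegas, `/`))), 1e-12)
  expect_lt(max(abs(crossprod(S, red$u_plus) -
                    sweep(red$u_minus, 2, red$omegas, `/`))), 1e-12)
})

test_that("solve_reduced flags degenerate or unstable reduced problems", {
  expect_error(solve_reduced(matrix(0, 2, 2), 1), class = "linresp_instability")
})

test_that("the swapped residual matches the dense full-space residual", {
  n <- 30
  p <- gen_problem(n, seed = 44, kind = "mcscf")
  cfg <- solver_config(3, seed = 44)
  # build a genuine solver state by running two iterations
  st <- local({
    guess <- gen_guess(p, 3)
    cnt <- linresp:::new_counter()
    s <- linresp:::smogd_expand(linresp:::new_subspace(n), guess, p,
                                ortho_config(), cnt)$state
    red <- solve_reduced(s$S, 3)
    R <- form_residual(s, red$omegas, red$u_plus, red$u_minus)
    cand <- precondition(p$diag_A, p$diag_Sigma, red$omegas, R)
    linresp:::smogd_expand(s, cand, p, ortho_config(), cnt)$state
  })
  red <- solve_reduced(st$S, 3)
  R <- form_residual(st, red$omegas, red$u_plus, red$u_minus)
  fo <- full_lambda_omega(p)
  x <- parity_embed(parity_block(st$Vp %*% red$u_plus, st$Vm %*% red$u_minus))
  Rdense <- parity_split(fo$Omega %*% x -
                         sweep(fo$Lambda %*% x, 2, red$omegas, `/`))
  expect_equal(R$plus, Rdense$plus, tolerance = 1e-12)
  expect_equal(R$minus, Rdense$minus, tolerance = 1e-12)

  # residual vanishes at an exact eigenpair contained in the subspace
  pd <- diag_tddft_problem(10)
  stx <- local({
    cnt <- linresp:::new_counter()
    linresp:::smogd_expand(linresp:::new_subspace(10), gen_guess(pd, 2), pd,
                           ortho_config(), cnt)$state
  })
  redx <- solve_reduced(stx$S, 2)
  Rx <- form_residual(stx, redx$omegas, redx$u_plus, redx$u_minus)
  expect_lt(max(abs(Rx$plus), abs(Rx$minus)), 1e-10)
})

test_that("the preconditioner solves the coordinate-wise 2x2 systems", {
  n <- 12
  set.seed(55)
  dA <- runif(n, 1, 3); dS <- runif(n, 0.5, 1.5)
  om <- c(0.8, 1.7)
  R <- parity_block(matrix(rnorm(n * 2), n), matrix(rnorm(n * 2), n))
  b <- precondition(dA, dS, om, R, floor = 1e-8)
  for (j in 1:2) for (i in 1:n) {
    M <- rbind(c(-dA[i] / om[j], dS[i]), c(dS[i], -dA[i] / om[j]))
    bb <- solve(M, -c(R$plus[i, j], R$minus[i, j]))
    expect_equal(c(b$plus[i, j], b$minus[i, j]), bb, tolerance = 1e-10)
  }
  # homogeneous system
  b0 <- precondition(dA, dS, om, parity_block(matrix(0, n, 2), matrix(0, n, 2)))
  expect_identical(max(abs(b0$plus), abs(b0$minus)), 0)
  # singular 2x2 (D_A/omega = D_Sigma = 1) is floored to a finite result
  bs <- precondition(1, 1, 1, parity_block(matrix(1), matrix(0.5)), floor = 1e-8)
  expect_true(all(is.finite(c(bs$plus, bs$minus))))
})

test_that("expand preserves Lambda-orthonormality and the S contract", {
  n <- 25
  p <- gen_problem(n, seed = 66, kind = "mcscf")
  cnt <- linresp:::new_counter()
  st <- linresp:::smogd_expand(linresp:::new_subspace(n), gen_guess(p, 3), p,
                               ortho_config(), cnt)$state
  set.seed(67)
  cand <- parity_block(matrix(rnorm(n * 2), n), matrix(rnorm(n * 2), n))
  st2 <- linresp:::smogd_expand(st, cand, p, ortho_config(), cnt)$state
  d <- p$dense
  expect_lt(max(abs(crossprod(st2$Vp, d$ApB %*% st2$Vp) - diag(5))), 1e-10)
  expect_lt(max(abs(crossprod(st2$Vm, d$AmB %*% st2$Vm) - diag(5))), 1e-10)
  # S entries equal from-scratch recomputation (b+_i)' (Sigma-Delta) b-_j
  expect_equal(st2$S, crossprod(st2$Vp, (d$Sigma - d$Delta) %*% st2$Vm),
               tolerance = 1e-12)
  # stored images stay consistent with fresh operator applications
  expect_equal(st2$LVp, d$ApB %*% st2$Vp, tolerance = 1e-12)
  expect_equal(st2$BVm, (d$Sigma - d$Delta) %*% st2$Vm, tolerance = 1e-12)
  # appending a zero block changes nothing
  st3 <- linresp:::smogd_expand(st2, parity_block(matrix(0, n, 2),
                                                  matrix(0, n, 2)),
                                p, ortho_config(), cnt)
  expect_identical(st3$added, c(0L, 0L))
  expect_identical(st3$state$S, st2$S)
})

test_that("a guess spanning an invariant subspace converges in one iteration", {
  p <- diag_tddft_problem(12)
  r <- smogd_solve(p, solver_config(3, guess_perturb = 0))
  expect_identical(r$iterations, 1L)
  expect_equal(r$omegas, c(1, 2, 3), tolerance = 1e-12)
  expect_identical(r$status, "converged")
})

test_that("converged eigenvalues match the dense oracle on a general problem", {
  p <- gen_problem(100, seed = 11, kind = "mcscf")
  r <- smogd_solve(p, solver_config(5, seed = 1, max_iter = 300))
  o <- dense_response_eig(p, 5)
  expect_identical(r$status, "converged")
  expect_lt(max(abs(r$omegas - o$omegas) / o$omegas), 1e-8)
  # assembled full-space vectors satisfy the pencil
  expect_lt(max(fullspace_residual_max(p, r)), 1e-5)
  # output normalization: x' Omega x = 1 per root
  fo <- full_lambda_omega(p)
  X <- rbind(r$y, r$z)
  expect_equal(colSums(X * (fo$Omega %*% X)), rep(1, 5), tolerance = 1e-8)
})

test_that("converged spectra are invariant under the restart policy", {
  p <- gen_problem(200, seed = 2, kind = "tddft")
  r20 <- smogd_solve(p, solver_config(10, seed = 2, guess_perturb = 0.01,
                                      max_space_per_root = 20))
  r10 <- smogd_solve(p, solver_config(10, seed = 2, guess_perturb = 0.01,
                                      max_space_per_root = 10))
  expect_identical(r20$status, "converged")
  expect_identical(r10$status, "converged")
  expect_lt(max(abs(r20$omegas - r10$omegas) / r20$omegas), 1e-8)
})

test_that("Ritz estimates decrease monotonically and stay above the truth", {
  p <- gen_problem(150, seed = 71, kind = "tddft")
  r <- smogd_solve(p, solver_config(4, seed = 71, guess_perturb = 0.01))
  o <- dense_response_eig(p, 4)
  expect_true(all(diff(r$ritz_history) <= 1e-10))
  expect_true(all(t(r$ritz_history) >= o$omegas - 1e-10))
})

test_that("TD-DFT solves use two operator applications per iteration", {
  p <- gen_problem(80, seed = 3, kind = "tddft")
  r <- smogd_solve(p, solver_config(4, seed = 3, guess_perturb = 0.01))
  log <- r$iter_log
  expect_true(all(log$mvp_batches[-1] == 2L))
  expect_identical(r$mvp_batches_guess, 2L)
})
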