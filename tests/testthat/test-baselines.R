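test_that("the Olsen reduced solve generalizes the metric-orthonormal one", {
  # with E = I the two reduced problems coincide
  set.seed(81)
  S <- matrix(rnorm(25), 5)
  ro <- olsen_solve_reduced(diag(5), diag(5), S, 2)
  rs <- solve_reduced(S, 2)
  expect_equal(ro$omegas, rs$omegas, tolerance = 1e-12)

  # m = 1 closed form: 1/omega = S / sqrt(E+ E-)
  expect_equal(olsen_solve_reduced(matrix(2), matrix(8), matrix(0.5), 1)$omegas,
               sqrt(2 * 8) / 0.5, tolerance = 1e-13)

  # random m = 5 pencil against a dense nonsymmetric solve
  Ep <- rand_spd_cond(5, 82); Em <- rand_spd_cond(5, 83)
  red <- olsen_solve_reduced(Ep, Em, S, 3)
  G <- rbind(cbind(Ep, matrix(0, 5, 5)), cbind(matrix(0, 5, 5), Em))
  M2 <- rbind(cbind(matrix(0, 5, 5), S), cbind(t(S), matrix(0, 5, 5)))
  mu <- Re(eigen(solve(G, M2))$values)
  expect_equal(red$omegas, sort(1 / sort(mu, decreasing = TRUE)[1:3]),
               tolerance = 1e-10)
})

test_that("Olsen reduced solve flags a non-PD metric", {
  S <- matrix(rnorm(4), 2)
  expect_error(olsen_solve_reduced(diag(c(1, -1)), diag(2), S, 1),
               class = "linresp_breakdown")
})

test_that("Olsen and SMO-GD produce equivalent iterations from one guess", {
  for (kind in c("tddft", "stress")) {
    p <- gen_problem(100, seed = 91, kind = kind)
    cfg <- solver_config(5, seed = 91, guess_perturb = 0.01)
    g <- gen_guess(p, 5, perturb = 0.01, seed = 91)
    r1 <- smogd_solve(p, cfg, guess = g)
    r2 <- olsen_solve(p, cfg, guess = g)
    expect_identical(r1$iterations, r2$iterations)
    expect_lt(max(abs(r2$ritz_history - r1$ritz_history) / r1$ritz_history),
              1e-9)
  }
})

test_that("Olsen converges to the dense oracle", {
  p <- gen_problem(100, seed = 11, kind = "mcscf")
  r <- olsen_solve(p, solver_config(5, seed = 1, max_iter = 300))
  o <- dense_response_eig(p, 5)
  expect_identical(r$status, "converged")
  expect_lt(max(abs(r$omegas - o$omegas) / o$omegas), 1e-8)
  # 1-iteration convergence on a diagonal problem
  rd <- olsen_solve(diag_tddft_problem(10), solver_config(3))
  expect_identical(rd$iterations, 1L)
})

test_that("SSF solves TD-DFT problems and matches the oracle", {
  rd <- ssf_solve(diag_tddft_problem(10), solver_config(3))
  expect_identical(rd$iterations, 1L)
  expect_equal(rd$omegas, c(1, 2, 3), tolerance = 1e-12)

  p <- gen_problem(150, seed = 4, kind = "tddft")
  r <- ssf_solve(p, solver_config(5, seed = 4, guess_perturb = 0.01))
  o <- dense_response_eig(p, 5)
  expect_identical(r$status, "converged")
  expect_lt(max(abs(r$omegas - o$omegas) / o$omegas), 1e-7)

  # per-iteration reduced-space cost: 2 diagonalizations, 5 multiplies
  expect_true(all(r$iter_log$ev_m == 2L))
  expect_true(all(r$iter_log$mm_m == 5L))
})

test_that("SSF performs twice the operator applications of SMO-GD", {
  p <- gen_problem(120, seed = 5, kind = "tddft")
  cfg <- solver_config(4, seed = 5, guess_perturb = 0.01)
  g <- gen_guess(p, 4, perturb = 0.01, seed = 5)
  rs <- ssf_solve(p, cfg, guess = g)
  # each unlocked root contributes two preconditioned directions
  expect_true(all(rs$iter_log$mvp_cols[-1] ==
                  2 * 2 * (4 - rs$iter_log$n_converged[-nrow(rs$iter_log)])))
})

test_that("SSF guards its domain and its reduced-space factorization", {
  pm <- gen_problem(20, seed = 6, kind = "mcscf")
  expect_error(ssf_solve(pm, solver_config(2)), "TD-DFT")
  # E- loses positive definiteness when A - B is indefinite
  bad <- dense_response_problem(diag(20), diag(c(rep(1, 19), -1)))
  expect_error(ssf_solve(bad, solver_config(2, guess_perturb = 0.01)),
               class = "linresp_breakdown")
})

test_that("all three solvers agree on the TD-DFT spectrum", {
  for (sd in c(101, 102, 103)) {
    p <- gen_problem(90, seed = sd, kind = "tddft")
    cfg <- solver_config(4, seed = sd, guess_perturb = 0.01)
    g <- gen_guess(p, 4, perturb = 0.01, seed = sd)
    w1 <- smogd_solve(p, cfg, guess = g)$omegas
    w2 <- olsen_solve(p, cfg, guess = g)$omegas
    w3 <- ssf_solve(p, cfg, guess = g)$omegas
    expect_lt(max(abs(w2 - w1) / w1), 1e-7)
    expect_lt(max(abs(w3 - w1) / w1), 1e-7)
  }
})
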