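# Fixture factories: every test problem is generated in code.

# n = 1 closed-form case: A = 2, B = 1, Sigma = 1, Delta = 0,
# omega = sqrt((A+B)(A-B)) = sqrt(3).
tiny_problem <- function() {
  dense_response_problem(ApB = matrix(3), AmB = matrix(1))
}

# random dense blocks with controlled symmetry, for hand-assembled oracles
rand_sym <- function(n, seed, scale = 1) {
  set.seed(seed)
  M <- matrix(runif(n * n, -1, 1), n)
  scale * (M + t(M)) / 2
}

# small SPD matrix with given condition number
rand_spd_cond <- function(n, seed, cond = 10) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(n * n), n)))
  d <- exp(seq(0, log(cond), length.out = n))
  Q %*% (d * t(Q))
}

# diagonal TD-DFT problem: A = diag(1..n), B = 0; exact eigenpairs are the
# canonical vectors with omega = i
diag_tddft_problem <- function(n) {
  dense_response_problem(ApB = diag(seq_len(n)), AmB = diag(seq_len(n)))
}

# residual of the full-space pencil for an assembled report, max-abs per root
fullspace_residual_max <- function(problem, report) {
  fo <- full_lambda_omega(problem)
  X <- rbind(report$y, report$z)
  R <- fo$Lambda %*% X - sweep(fo$Omega %*% X, 2, report$omegas, `*`)
  apply(abs(R), 2, max) / sqrt(colSums(X^2))
}
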