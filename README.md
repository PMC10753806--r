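# linresp

Iterative eigensolvers for the linear-response equations of quantum
chemistry — the paired generalized eigenvalue problem

```
Λ x = ω Ω x,    Λ = [[A, B], [B, A]],    Ω = [[Σ, Δ], [−Δ, −Σ]]
```

whose positive eigenvalues ω are excitation energies (Hartree–Fock,
TD-DFT, MCSCF) and whose eigenvectors carry transition properties.  The
blocks A, B, Σ are symmetric, Δ is antisymmetric, and A+B, A−B, Σ are
positive definite for a stable ground state — but the metric Ω is
indefinite, which rules out the standard Cholesky reduction to a
symmetric eigenproblem.

The package is aimed at people developing or studying response-equation
solvers: it provides desk-scale, fully instrumented implementations whose
operation counts and convergence behavior can be measured and compared,
with matrix-free operators supported on the same footing as dense ones.

## What is inside

* **`smogd_solve`** — the package's main solver (Swapped-Metric-Orthogonal
  Generalized Davidson).  Since Λ is positive definite, the pencil is
  rewritten as Ω x = (1/ω) Λ x and the symmetric/antisymmetric expansion
  vectors are kept orthonormal in the Λ inner product.  The projected
  problem then collapses to a *half-size symmetric* eigenproblem

  ```
  S Sᵀ u⁺ = (1/ω²) u⁺,   u⁻ = ω Sᵀ u⁺,   S_ij = (b_i⁺)ᵀ (Σ−Δ) b_j⁻
  ```

  so each iteration needs only one m-sized matrix product and one
  m-sized symmetric diagonalization (m = subspace size) — plus the same
  four operator applications per iteration as the classical algorithms
  (two in TD-DFT mode).
* **`olsen_solve`** — the classical paired-Davidson reference solver
  (Euclidean-orthonormal expansion vectors, 2m-sized generalized reduced
  problem).
* **`ssf_solve`** — the Strattmann–Scuseria–Frisch solver for the TD-DFT
  case (single nonfaithful subspace, symmetrized E⁻E⁺ reduced problem).
* **`gen_problem` / `gen_guess`** — a seeded generator of synthetic
  response problems with the right structure (diagonally dominant SPD
  A±B, Gram-matrix Σ, antisymmetric Δ; TD-DFT and stress variants), and
  the canonical / perturbed start guesses.
* **`dense_response_eig`** — a dense full-space reference solver used as
  the oracle by every test, with an independent cross-check route.
* **`run_experiment`** — a benchmark harness running several solvers from
  identical guesses and recording iteration counts and instrumented
  operation counters.
* Matrix Market + JSON-manifest I/O (`write_problem`, `read_problem`),
  JSONL iteration logs, and thin command-line wrappers under
  `inst/cli/` (`respgen.R`, `respsolve.R`, `resporacle.R`, `respbench.R`).

## Worked example

```r
library(linresp)

problem <- gen_problem(n = 300, seed = 7, kind = "tddft")
config  <- solver_config(n_eig = 4, seed = 7, guess_perturb = 0.01)
report  <- smogd_solve(problem, config)
report
#> <solve_report> smogd: n = 300, 4 roots, 11 iterations (converged)
#>   omega: 0.99109100 0.99533029 0.99898641 1.00285279
#>   converged: 4/4; MVP batches 22 (columns 66)
#>   m-sized ops: EV 11, MM 11, SVD 0, CD 0; small CD 45; max sweeps 2

oracle <- dense_response_eig(problem, 4)
cbind(iterative = report$omegas, dense = oracle$omegas)
#>      iterative     dense
#> [1,] 0.9910910 0.9910910
#> [2,] 0.9953303 0.9953303
#> [3,] 0.9989864 0.9989864
#> [4,] 1.0028528 1.0028528
```

Reading the output: the four lowest excitation energies of a TD-DFT-like
problem of half-dimension 300 converged in 11 iterations from a noisy
canonical guess.  `MVP batches 22` is the operator-application count
(2 per iteration in TD-DFT mode, including the start guess); the
m-sized dense operations are exactly one symmetric diagonalization (EV)
and one matrix–matrix multiply (MM) per iteration, with no SVDs and no
m-sized Cholesky factorizations — the cost signature that distinguishes
this algorithm.  The `small CD` count covers the n_eig-sized
orthogonalization factors, and `max sweeps 2` records that iterated
projection/orthonormalization never needed more than two sweeps.  The
eigenvalues match the dense reference to the digits shown.

Per-iteration eigenvalue and residual histories are in
`report$ritz_history`, `report$rms_history`, `report$max_history`;
assembled full-space eigenvectors (normalized to xᵀΩx = 1) in
`report$y` and `report$z`.

## Scope

No shift-and-invert, no interior roots, no complex response, and no
construction of response matrices from electronic-structure integrals —
the generator emulates their structure statistically.  See the methods
vignette (`vignettes/linresp-methods.Rmd`) for the algorithms, the
conventions (residual norms, locking, restarts, normalization), and the
design decisions.
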