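---
title: "Solving the linear-response eigenvalue problem with metric-orthogonal expansion vectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solving the linear-response eigenvalue problem with metric-orthogonal expansion vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linresp)
```

## The problem

Excitation energies in Hartree–Fock, TD-DFT and MCSCF response theory are
the positive eigenvalues of the paired pencil

$$\Lambda x = \omega \, \Omega x, \qquad
\Lambda = \begin{pmatrix} A & B \\ B & A \end{pmatrix}, \qquad
\Omega = \begin{pmatrix} \Sigma & \Delta \\ -\Delta & -\Sigma \end{pmatrix},$$

with $A$, $B$, $\Sigma$ symmetric $n \times n$ blocks, $\Delta$
antisymmetric, and $A+B$, $A-B$, $\Sigma$ positive definite whenever the
underlying ground state is stable.  For Hartree–Fock and TD-DFT,
$\Sigma = I$ and $\Delta = 0$.  The metric $\Omega$ is symmetric but
*indefinite*: its Cholesky factor does not exist, so the textbook
reduction to a standard symmetric eigenproblem is unavailable, and the
spectrum comes in $\pm\omega$ pairs — if $(\omega, (y, z))$ solves the
pencil, so does $(-\omega, (z, y))$.

All solvers in this package exploit the pairing by expanding candidate
eigenvectors in *symmetric* vectors $v^{(+)} = (v^+, v^+)$ and
*antisymmetric* vectors $v^{(-)} = (v^-, -v^-)$.  In this basis
$\Lambda$ preserves parity ($\Lambda v^{(+)}$ is symmetric with half-size
component $(A+B)v^+$) while $\Omega$ swaps it, so all subspace algebra can
be done on half-size blocks; full $2n$-vectors exist only at I/O
boundaries and inside the dense reference solver.

## The swapped-metric solver

Because $\Lambda$ is positive definite under the stability assumption,
the pencil can be inverted to

$$\Omega x = \frac{1}{\omega} \Lambda x,$$

which *does* have an SPD metric.  The package's main solver keeps the
per-parity expansion blocks $V^\pm$ orthonormal in the induced inner
product $\langle v, w\rangle_\Lambda$, i.e.
$(V^+)^T (A+B)\, V^+ = (V^-)^T (A-B)\, V^- = I$.  The projected problem
then loses its metric entirely and, thanks to the parity block structure,
collapses to the *half-size symmetric* eigenproblem

$$S S^T u^+ = \frac{1}{\omega^2} u^+, \qquad
  u^- = \omega\, S^T u^+, \qquad
  S_{ij} = (b_i^+)^T (\Sigma - \Delta)\, b_j^-.$$

Per outer iteration the only dense operations at the subspace size $m$
are one matrix–matrix product ($S S^T$) and one symmetric
diagonalization — the instrumentation counters in every `solve_report`
verify exactly `1 EV, 1 MM, 0 SVD, 0 CD` of size $m$ per iteration.  The
two extra orthogonalizations cost only $O(n\,m\,n_\mathrm{eig})$ work
with $n_\mathrm{eig}$-sized Cholesky factors, which are counted
separately.

One iteration performs, in order:

1. **Reduced solve** (`solve_reduced`): diagonalize $S S^T$, keep the
   $n_\mathrm{eig}$ largest eigenvalues $1/\omega^2$.
2. **Residual** (`form_residual`): the swapped-form residual
   $R = \Omega x - \Lambda x/\omega$ splits by parity into
   $R^+ = (BV^-) u^- - (LV^+) u^+ / \omega$ and
   $R^- = (BV^+) u^+ - (LV^-) u^- / \omega$, assembled entirely from the
   stored operator images ($\sigma$ and $\tau$ vectors); no operator
   applications.
3. **Convergence test**: see the conventions below; converged roots are
   locked — they stay in the subspace and keep being recomputed, but
   contribute no new expansion directions.
4. **Preconditioning** (`precondition`): the diagonal approximation of
   the correction equation couples only the two parity components of one
   coordinate, so each coordinate solves a $2 \times 2$ system
   $[[-D_{A,i}/\omega,\; D_{\Sigma,i}], [D_{\Sigma,i},\; -D_{A,i}/\omega]]
   (b_i^+, b_i^-) = -(R_i^+, R_i^-)$.  Determinants below `precond_floor`
   (default $10^{-8}$) are replaced by `sign(det) * floor`
   (with $\mathrm{sign}(0) = +1$), so the solve never breaks down near
   $D_{A,i}/\omega = D_{\Sigma,i}$.
5. **Expansion**: candidates are projected against $V^\pm$ *in the
   $\Lambda$ inner product* using the stored images (free of operator
   cost), orthonormalized by iterated Cholesky of their overlap, then —
   after the iteration's only response-matrix applications
   $(A \pm B)\,b$ — $\Lambda$-orthonormalized by a Cholesky factorization
   of the small metric overlap $M^\pm = W^T (A\pm B) W$, with the images
   transformed by the same triangular factor rather than recomputed.
   For a single vector $M^\pm$ is a scalar and the factor its square
   root.  Performing the Euclidean orthonormalization first keeps
   $M^\pm$ well conditioned, which is what makes the metric step safe
   near convergence.

In the general case this costs exactly four operator batches per
iteration ($\sigma^\pm$ and $\tau^\pm$); in TD-DFT mode the $\tau$
updates are copies and only two batches remain.

### Why project in the $\Lambda$ inner product

The identity reduced metric — and hence the half-size symmetric reduced
problem — holds only if the *whole* basis is $\Lambda$-orthonormal,
old and new columns alike.  A Euclidean-only projection would leave
nonzero old–new $\Lambda$ cross terms.  Since the images
$LV^\pm$ are stored anyway, the $\Lambda$-projection
$W \leftarrow W - V^\pm\,(LV^\pm)^T W$ costs nothing extra.  The sweep
stops when the cross-product magnitude falls below `proj_threshold`
($10^{-12}$); the test suite asserts that two sweeps always suffice on
the instance families shipped here.

### Numerical safeguards

* Candidate columns that lose more than ten orders of magnitude of their
  norm under projection (`drop_tol` $= 10^{-10}$) are dropped as
  linearly dependent — the root simply contributes no new direction that
  iteration.  If *all* candidates drop and nothing converged, the solver
  raises a stagnation error instead of looping.
* A Cholesky factorization that fails on a near-singular overlap is
  retried once with a relative diagonal shift (`chol_retry_shift`
  $= 10^{-14}$); needing the shift at all is treated as a rank-deficiency
  signal in the strict user-facing `ortho_cd`, while the solver-internal
  path falls back to a pivoted factorization and keeps an independent
  column subset.  With Gram-matrix-based orthonormalization the squared
  conditioning means blocks beyond $\kappa(W) \sim 10^8$ cannot be
  certified full rank; this is an intrinsic limit of Cholesky-based
  orthogonalization, documented rather than hidden.
* A nonpositive eigenvalue of $S S^T$ means the stability assumption is
  violated or the subspace degenerate; the solver raises an instability
  error (this doubles as the $\omega \neq 0$ guard).

### Locking, thick restart, ordering

The subspace is capped at `max_space_per_root` $\times\ n_\mathrm{eig}$
columns per parity (default 20, matching the protocol used in the
comparison experiments).  When the cap would be exceeded, each parity
block collapses onto the current Ritz components, re-orthonormalized in
the $\Lambda$ inner product with images transformed consistently (no new
operator applications), and the newest preconditioned candidates are
appended right after — a thick restart.  Because the collapsed space
contains the previous Ritz vectors, the monotone (Hylleraas–Undheim–
McDonald) decrease of every $\omega$ estimate survives restarts; the
test suite checks nonincrease per root to $10^{-10}$ slack together with
the lower bound given by the dense reference values.  Degenerate or
clustered roots are ordered by $\omega$, ties by reduced-vector index,
and convergence is assessed per root.

### Conventions (they matter for comparability)

* **Residual norms.**  A root is converged when the *standard-form*
  full-space residual $\Lambda x - \omega \Omega x$ has RMS below
  `tol_rms` over all $2n$ components and max-abs below `tol_max`
  (defaults $10^{-6}$ / $10^{-5}$), with $x$ scaled to unit coefficient
  norm in a $\Lambda$-orthonormal basis.  The swapped-form residual the
  solver assembles is rescaled by $\omega$ for this test.  All three
  solvers use the identical convention; without it the cross-solver
  iteration counts would not be comparable, since the swapped and
  standard residuals differ by a factor $\omega$ per root.
* **Iteration count** = number of reduced solves; a guess that spans an
  invariant subspace therefore converges in one iteration.
* **Output normalization.**  Converged vectors are returned with
  $x^T \Omega x = 1$ (the $\Omega$-bilinear form is positive at
  convergence for the positive-$\omega$ branch) and the sign fixed by
  making the largest-magnitude component of $(y, z)$ positive.
* **Start guess.**  Canonical basis vectors at the $n_\mathrm{eig}$
  smallest entries of $\mathrm{diag}(A)$ (ties toward the lower index),
  with equal parity components; this is also used for general-metric
  problems, $\Lambda$-orthonormalized on entry.  `guess_perturb` adds one
  seeded uniform $[0, \mathrm{perturb}]$ noise vector per guess vector to
  both components, so all solvers start from the same full-space guess.

## Baselines

**Olsen solver** (`olsen_solve`): the classic paired-Davidson algorithm.
Expansion blocks are Euclidean-orthonormal, so the projected problem
keeps the reduced response blocks
$E^\pm_{ij} = (b_i^\pm)^T (A \pm B) b_j^\pm$ as an SPD metric:
$[[0, S], [S^T, 0]]\,u = \tfrac{1}{\omega}\,\mathrm{diag}(E^+, E^-)\,u$,
solved per iteration with one $2m$ Cholesky plus one $2m$ symmetric
diagonalization (the swapped $1/\omega$ form is used precisely so the
metric is SPD).  The preconditioner solves
$(D_\Lambda - \omega D_\Omega) b = -R$ coordinate-wise.  Started from
the same guess, the Olsen and metric-orthogonal solvers generate the
same subspaces in exact arithmetic — the preconditioned directions can
be shown to coincide algebraically, since
$R_\mathrm{std} = -\omega R_\mathrm{swap}$ and
$D_\Lambda - \omega D_\Omega = -\omega (D_\Omega - D_\Lambda/\omega)$ —
so the per-iteration Ritz values agree to roundoff.  The test suite
asserts this to $10^{-9}$ relative, with one caveat: on general-metric
instances with tightly clustered spectra the rotational freedom of
near-degenerate Ritz subspaces amplifies roundoff differently along the
two algebraic routes, and the per-iteration match decays with iteration
count even though both solvers converge to final spectra agreeing to
$\sim 10^{-13}$.  Those cells are therefore held to final-spectrum
agreement.

**SSF solver** (`ssf_solve`, TD-DFT only): one Euclidean-orthonormal
subspace carries both components (a nonfaithful representation that
becomes exact at convergence).  The reduced problem
$E^- E^+ u^+ = \omega^2 u^+$ is non-Hermitian and is solved through the
symmetrized form $(E^-)^{1/2} E^+ (E^-)^{1/2}$: per iteration two
$m$-sized diagonalizations and five $m$-sized multiplications
(square root of $E^-$; two to build the symmetrized matrix; two to
recover $u^+$ and the left eigenvectors $u^-$, which are then
biorthonormalized by a per-root scaling).  Each unlocked root
contributes *two* preconditioned directions (right and left residual),
so SSF performs twice the operator applications of the metric-orthogonal
solver per iteration.  If $E^-$ loses positive definiteness the solver
raises a breakdown error — the known fragility of the approach on barely
diagonally dominant problems; the expansion details beyond the reduced
solve follow the generic paired-Davidson pattern and are deliberately
approximate, with the instrumented operation counts as the contract.

The Helmich-Paris reduction (two SVDs, two Cholesky factorizations,
eight multiplications per iteration at size $m$) is *not* implemented;
its cost profile is recorded here only as context for the operation
counters.

## The dense reference solver

`dense_response_eig` assembles the full pencil, factors
$\Lambda = U^T U$, and diagonalizes $U^{-T} \Omega\, U^{-1}$ — the same
swapped-metric observation applied in dense arithmetic — returning the
smallest positive $\omega$ with back-transformed eigenvectors, and
validating the $\pm$ pairing of the spectrum as a side assertion.  A
slower nonsymmetric pencil route (`method = "pencil"`) and, for TD-DFT,
the half-size closed form
$\omega^2 = \mathrm{eig}\!\left((A-B)^{1/2}(A+B)(A-B)^{1/2}\right)$
serve as independent cross-checks; the test suite requires the routes to
agree to $10^{-10}$ relative.  Dense assembly is guarded to
$n \le 5000$.

## The synthetic problem generator

Real response matrices are unavailable without an electronic-structure
code, so the generator emulates their statistical structure:

* `gen_spd_pair`: $A+B$ and $A-B$ have off-diagonal entries uniform on
  $[0, 0.01]$ (symmetrized) and diagonal $1 + (i-1)/n$ — strongly
  diagonally dominant SPD matrices whose diagonal grows linearly, a
  caricature of a well-conditioned orbital-Hessian spectrum.
* `gen_metric`: $\Sigma = G G^T / n$ with $G$ uniform on $[0,1)$
  (SPD almost surely; the $1/n$ keeps conditioning moderate) and
  $\Delta = 0.01\,(G' - G'^T)$, exactly antisymmetric.  The
  $\Delta$ scale is a package choice — nothing in the emulated setting
  fixes it — chosen once so the full metric stays comfortably
  invertible at the sizes tested, and configurable.
* `gen_problem` kinds: `"mcscf"` (both of the above), `"tddft"`
  ($\Sigma = I$, $\Delta = 0$), and `"stress"` — fully random symmetric
  blocks with the diagonal shifted so the smallest eigenvalue is 0.1,
  i.e. barely diagonally dominant problems that exercise solver
  robustness.

All randomness flows through one master seed per object, spawning
per-matrix streams from R's Mersenne–Twister; identical `(n, seed,
kind)` yield bit-identical problems.  What the generator does *not*
emulate: degeneracy patterns from molecular symmetry, the sparsity and
magnitude structure of real two-electron integrals, and metric blocks of
genuine MCSCF calculations.  Passing tests therefore demonstrate
correctness of the linear algebra and the claimed cost/convergence
structure on matrices with the right symmetry, definiteness and
dominance properties — not accuracy for any particular molecule.

A consequence worth knowing: the Gram-matrix $\Sigma$ of the `"mcscf"`
family is *not* diagonally dominant, so the diagonal preconditioner is
poor there and convergence is slow with tight subspace caps.  The
oracle-equivalence tests run those instances with a cap of 60 vectors
per root and up to 600 iterations — a solver-budget choice, not a change
to the algorithm — and all instances then converge to the reference
values within $10^{-8}$ relative.

## Problem sizes used by the shipped checks

The test suite verifies oracle equivalence on 27 instances
($n \in \{50, 100, 300\}$, all three kinds,
$n_\mathrm{eig} \in \{1, 5, 10\}$).  The convergence-comparison protocol
(canonical guess perturbed by uniform $[0, 0.01]$ noise, tolerances
$10^{-6}$ RMS / $10^{-5}$ max, cap 20 per root) runs at $n = 1000$ with
$n_\mathrm{eig}$ from 10 to 100 in steps of 10 over five seeds, and the
acceptance script reports the *modal* iteration count per solver over
that sweep, resolving ties toward the sample median.  At this scale the
high-$n_\mathrm{eig}$ cells saturate the half-space ($m$ approaches
$n$), which accelerates their convergence relative to runs at much
larger $n$; the mid-range cells are free of this finite-size effect.
The robustness checks use `"stress"` instances at $n = 80$, including a
$10^{-10}$-RMS tight-tolerance variant.

## Known limitations

* No shift-and-invert or interior-root targeting; only the lowest
  excitation energies are accessible.
* No complex-valued (imaginary-perturbation) response, and no
  linear-equation (property gradient) mode.
* The dense reference path and the generator are dense-only; matrix-free
  operators are first-class for the iterative solvers but must be
  supplied by the user.
* Cholesky-based orthonormalization cannot certify rank below
  $\kappa(W) \approx 10^8$ (see above); an SVD/QR path is deliberately
  out of scope.
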