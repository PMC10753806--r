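Package: linresp
Title: Iterative Eigensolvers for Linear-Response Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solvers for the paired generalized eigenvalue problem of
    linear-response theory (Hartree-Fock, TD-DFT, MCSCF excitation
    energies).  Implements the Swapped-Metric-Orthogonal Generalized
    Davidson (SMO-GD) algorithm, which works with expansion vectors that
    are orthonormal in the inner product induced by the response matrix so
    that the reduced problem becomes a half-size symmetric eigenproblem,
    together with the classic Olsen reduced-space solver and the
    Strattmann-Scuseria-Frisch (SSF) solver for the TD-DFT case.  Includes
    a structured random-problem generator, a dense full-space reference
    solver, Matrix Market input/output, and an instrumented benchmark
    harness that records operation counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    methods,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
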