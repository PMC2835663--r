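Package: seldiv
Title: Sequence Divergence Dynamics Under Constant Selection
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the divergence of two independently evolving sequences
    under constant selection in the weak-mutation regime. Builds
    allele-replacement (origin-fixation) rate matrices from per-site mutation
    rates and scaled selection coefficients, solves for equilibrium allele
    frequencies and the asymptotic divergence, integrates the exact pair
    dynamics of mismatch frequencies, and summarises divergence curves by
    half-approach periods, effective relaxation rates and deceleration
    ratios. Includes closed-form neutral and two-allele solutions, the
    Jukes-Cantor correction, a stochastic per-site simulator with FASTA
    output, parameter sweeps over selection regimes and random mutation
    matrices, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    ape,
    yaml,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
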