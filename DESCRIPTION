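Package: cdropt
Title: Energy-Based Multi-Objective Optimization of Antibody CDR Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative design of antibody complementarity-determining-region
    (CDR) variants by sampling from a Boltzmann distribution whose energy is a
    linear scalarization of predicted binding affinity (Gaussian-process
    regression over sequence embeddings with an upper/lower-confidence-bound
    acquisition), predicted solubility (hydrophobicity-weighted solvent
    accessibility), and an autoregressive humanness prior. Provides
    Metropolis-Hastings sampling over constrained mutation neighborhoods with
    Gelman-Rubin burn-in selection, an amortized GFlowNet-style sampler trained
    with a trajectory-balance objective, Pareto-front extraction and
    distance-based candidate selection, developability scores (charge,
    instability), baselines (constrained local search, random mutants), and a
    fully synthetic epistatic fitness landscape for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
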