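Package: recflip
Title: Resource-Decoupling Recombinase Controllers for Synthetic Gene Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic ODE model of two fluorescent-reporter gene modules
    competing for a shared pool of gene-expression resources in E. coli, with
    serine integrase/excisionase (Bxb1) mediated promoter inversion acting as
    a recombinase-based negative-feedback controller, optionally augmented by
    a feedforward branch that redirects the flipped promoter toward GFP.
    Provides steady-state dose-response scans over the L-arabinose induction
    ladder, parameter sweeps over feedback strength and excisionase turnover,
    the Coupling Index statistic (baseline-normalized GFP against
    max-normalized RFP, monotone piecewise-cubic fit, mean deviation from the
    ideal flat line), controller tuning by root finding on the Coupling
    Index, a synthetic plate-reader data generator, and parameter recovery
    from synthetic replicate data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
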