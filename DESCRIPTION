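Package: flagsync
Title: Hydrodynamic Synchronization Analysis for Pairs of Beating Flagella
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying purely hydrodynamic synchronization of
    eukaryotic flagella. Evaluates and fits point-force (Stokeslet) flow
    fields to planar velocity snapshots, reconstructs propulsive forces
    from tracked flagellar waveforms by resistive force theory with
    Lighthill drag coefficients, extracts beat phases by Poincare
    sectioning and characterises phase-locking, slips and their
    fluctuation statistics, fits the stochastic Adler model of the
    interflagellar phase difference and the 1/L scaling of the coupling
    strength, and simulates a minimal pair of Oseen-coupled spheres
    driven along compliant circular orbits. A seeded synthetic-data
    module generates flow snapshots, beating waveforms and coupled noisy
    phase pairs with known ground truth so that every analysis stage can
    be validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
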