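Package: dimerTPT
Title: Two-Layer Kinetic Transition Networks for Protein Homodimer Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a two-chain Wako-Saito-Munoz-Eaton (WSME) Ising-like
    folding model of a protein homodimer from a structure (or a synthetic toy
    description), assembles the two-layer kinetic transition network in which
    every conformation pair has one dissociated and one associated microstate,
    and applies discrete Transition Path Theory to quantify the reactive-flux
    contributions of induced folding, conformational selection and rigid
    docking to dimer formation. Also computes association-flux maps over
    per-chain folding degrees, per-segment foldedness at the moment of
    association, and scans over the dissociation entropy (a proxy for protein
    concentration). Includes a seeded Monte Carlo trajectory sampler used as
    an independent oracle for committors and flux observables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
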