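Package: refinecomplex
Title: Interface-Driven Refinement of Protein-Protein Complex Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines protein-protein complex model structures, such as those
    produced by rigid-body docking, by iterative Monte Carlo repacking of
    interface side chains followed by short restrained molecular-dynamics
    relaxations under a simulated-annealing temperature schedule. Supports
    two restraint protocols (distance-only and distance-plus-position),
    symmetric refinement of Cn homo-oligomers, ensemble generation with
    lowest-energy model selection, and CAPRI-style model quality assessment
    (ligand RMSD, interface RMSD, fraction of native contacts and the
    high/medium/acceptable/incorrect classification). Includes a synthetic
    fixture generator that builds idealized helical toy complexes and decoys
    of controlled accuracy so the full pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
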