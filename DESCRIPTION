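Package: polycollapse
Title: Coarse-Grained Langevin Dynamics and Coarsening Analysis of
    Collapsing Macromolecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implicit-solvent Langevin molecular dynamics for bead-spring
    models of polymers in tunable solvent quality, together with a
    coarsening-characterization pipeline for the collapse in bad solvent.
    Builds linear chains, star polymers, diamond-lattice and disordered
    (in-cavity cross-linked) microgel networks; integrates the equations of
    motion with a Gronbech-Jensen-Farago Langevin scheme; and analyses
    particle trajectories through a smoothed density field: chord-length
    distributions and relative domain size, cluster fractal statistics and
    normalized growth curves, and spin self-correlation functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
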