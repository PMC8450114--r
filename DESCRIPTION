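Package: holocsim
Title: Loop-Extrusion and Polymer Simulation of Holocentric Chromosome Condensation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-level model of mitotic chromosome condensation for holocentric
    and monocentric chromosomes. A 1D stochastic lattice simulation of two-sided
    loop extruders (SMC-complex stand-ins) with lifetime-limited residence,
    mutual blocking, and three modes of interaction with centromeric nucleosomes
    (none, blocking, anchoring) is coupled to a coarse-grained Langevin polymer
    simulation of the 10 nm chromatin fibre, optionally with a fixed kinetochore
    plate tethered to the centromeric line. Includes compaction metrics (axial
    nucleosomes, loop lengths, equilibrium detection), 3D structure analytics
    (centromere spacing, axial spacing, contact matrices, contact probability
    curves, groove profiles), experiment presets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
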