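Package: VariantLens
Title: Structure-Guided Interpretation of Missense Variants in
    Nucleotide-Binding Proteins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the structural impact of a missense variant
    on a protein model pair (wild type versus mutant): Walker A / P-loop
    motif annotation, Kabsch superposition and per-atom displacement
    profiling, van der Waals steric-clash detection, side-chain rotamer
    enumeration with clash scoring, hydrogen-bond and salt-bridge
    inventories with a charge-class energy scale, and equilibrium
    protonation patterns from finite-difference linear Poisson-Boltzmann
    electrostatics with grid focusing followed by exact or Metropolis
    Monte Carlo multi-site titration. Includes a synthetic-structure
    generator producing fixtures with analytic ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    bio3d,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
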