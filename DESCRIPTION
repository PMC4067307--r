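Package: digiprey
Title: Desk-Scale Digital Evolution of Anti-Predator Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An agent-based digital-evolution laboratory for studying how
    evolutionary history and standing genetic variation shape the evolvability
    of anti-predator behavior. Self-replicating digital organisms carry
    instruction-sequence genomes over a 60-symbol alphabet and live on a
    bounded resource grid where predation can evolve via an attack
    instruction. The package implements the full three-phase experimental
    design (open-ended evolution with or without predators; prey purification
    and standing-variation construction; pairwise competitions and trait
    assays against static predators), together with the metrics (Shannon
    diversity, Needleman-Wunsch alignment divergence, trait-proportion
    deltas) and a from-definition PerMANOVA used to analyse the outcomes.
    Includes synthetic-population generators, FASTA-dialect snapshot I/O,
    YAML run configuration, and deterministic seeded simulation throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
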