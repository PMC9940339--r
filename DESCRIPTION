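Package: scafgen
Title: Scaffold-Constrained De Novo Molecule Generation with
    Multi-Objective Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grows and links BRICS-derived fragment scaffolds into complete
    drug-like molecules with sequence- and graph-based encoder-decoder
    generators.  The graph generator emits a five-row adjacency-style matrix
    under stepwise valence masking, which guarantees that every sampled
    matrix decodes to a chemically valid molecule.  Generators are optimized
    by Pareto-ranked multi-objective policy-gradient reinforcement learning
    against drug-likeness and predicted bioactivity objectives, and generated
    populations are evaluated with validity, accuracy, desirability,
    uniqueness, novelty and Solow-Polasky diversity.  Cheminformatics
    primitives (SMILES parsing, BRICS fragmentation, fingerprints, QED and
    synthetic-accessibility scores) are delegated to RDKit through a batched
    command-line bridge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with RDKit, reachable as 'python'
Imports:
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
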