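Package: trefoilscan
Title: Structure-Guided Fold Expansion Analysis for the Beta-Trefoil Fold
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for bottom-up, structure-first surveys of the beta-trefoil
    fold: filtering of structure-search hit tables (DALI- and Foldseek-style
    dialects), Kabsch superposition with a sequence-independent dynamic
    programming aligner and reference-based structural multiple alignment,
    domain-architecture novelty classification, gap-filtered Shannon-entropy
    mutation-tolerance profiling, and distance-based phylogenetics with
    clade-purity statistics. Includes a seeded synthetic-data generator that
    produces trefoil-like structure families with planted ground truth so the
    whole pipeline can be exercised end to end without external searches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
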