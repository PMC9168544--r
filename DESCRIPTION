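Package: triadminer
Title: Acidic-Triad Ferroxidase Discovery, Phylogeny and Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies LPR1-type multicopper-oxidase ferroxidases by a
    degenerate three-motif acidic-triad signature, filters homology-search
    hits with the published thresholds, screens candidates with a
    position-specific scoring profile, builds distance-based midpoint-rooted
    bootstrap trees to test whether a streptophyte clade is nested within a
    bacterial radiation (the horizontal-gene-transfer topology), and fits
    Michaelis-Menten kinetics to ferrozine-assay ferroxidase data. Includes
    seeded synthetic-data generators for every stage so the full pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
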