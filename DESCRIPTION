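Package: stereoactivity
Title: Stereochemistry and Bioactivity Divergence in Small-Molecule Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to quantify how stereochemistry relates to small-molecule
    bioactivity. The package identifies groups of stereoisomers in a compound
    library via InChIKey connectivity-layer matching with exhaustive-
    characterization filters, compares ternary target-binding profiles within
    groups (distinct-profile counts, Jaccard distance distributions,
    Mann-Whitney tests), generates single MMFF94-optimized 3D conformers by
    seeded distance-geometry embedding, computes stereo-blind 2D circular
    fingerprints and a chirality-aware 3D geometric descriptor, and benchmarks
    how well each descriptor recapitulates bioactivity nearest-neighborhoods
    (percentile-defined neighbors, random and stringent negatives, AUROC).
    A synthetic library generator with controllable stereo-sensitivity makes
    the whole pipeline testable without external databases. Chemistry
    primitives (canonicalization, InChI, ECFP, MMFF94) are delegated to Open
    Babel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel (>= 3.0, the obabel executable on PATH)
Config/testthat/edition: 3
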