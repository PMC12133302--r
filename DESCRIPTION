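Package: fibrilbeta
Title: Structure-Based Beta-Sheet Preference Profiles for Amyloid Fibril
    Polymorphs
Version: 0.1.0
Authors@R:
    person("fibrilbeta", "authors", email = "maintainer@fibrilbeta.org",
           role = c("aut", "cre"))
Description: Builds experimental, structure-based beta-sheet preference
    profiles F-beta(n) from ensembles of amyloid fibril structures
    (coordinate files or curated strand-interval annotations), extracts
    high-preference sequence segments, and quantifies their agreement with
    sequence-based aggregation-propensity predictions (ZYGGREGATOR,
    AGGRESCAN, TANGO, WALTZ, PASTA 2.0 hot spots) through contingency
    tables, Cohen's kappa and a one-tail Fisher's exact test. Includes a
    synthetic-data generator that plants beta-core segments with
    per-residue flip noise and realises mock backbone coordinates from
    specified dihedral angles, so the whole pipeline is testable at desk
    scale.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
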