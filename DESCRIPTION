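Package: clonecna
Title: Clonal Evolution Analysis from Longitudinal SNP-Array Copy-Number Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracking clonal evolution of cultured cell populations
    across serial passages using SNP-array-like copy-number signals.  The
    package simulates branching clonal evolution under knockout-specific
    chromosomal-instability regimes (selection, drift, passage bottlenecks,
    whole genome duplication), emulates probe-level logR/BAF signals for
    clone mixtures, segments the signals and calls copy-number alteration
    events with a minimum-size filter and a clone-size detectability floor,
    estimates the mutated cell fraction (MCF) of every event in every sample,
    detects whole genome duplication by ploidy grid search, reconstructs
    subclone phylogenies under MCF containment and pigeonhole constraints
    with an exhaustive oracle for small instances, derives fishplot layout
    data for clonal dynamics, and compares event counts between groups with
    exact rank-sum tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
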