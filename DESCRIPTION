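Package: flankQuant
Title: Flank-Anchored Quantification of CRISPR Editing Outcomes from
    Amplicon Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies amplicon-sequencing reads of a CRISPR-edited locus
    by locating two short flank anchors (with a per-flank mismatch
    allowance) that delimit an editing window, calls insertions and
    deletions from window-length deviations, tabulates per-position base
    frequencies over intact windows, and estimates the frequency of a
    programmed knock-in edit. Includes a seeded synthetic read-pool
    simulator with a per-base substitution error model for validating the
    estimator by parameter recovery, plus small quantification helpers for
    downstream cell assays (phospho/total protein percentages, cell
    orientation under flow, area-under-curve readouts, vessel-diameter
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Sequencing, CRISPR, Alignment, QualityControl
RoxygenNote: 7.3.3
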