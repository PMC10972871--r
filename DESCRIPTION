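Package: skimsize
Title: Monoploid Genome Size Estimation from Low-Coverage Genome Skims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates monoploid (1Cx) genome size from very-low-coverage
    short-read genome skims by mapping translated reads onto a set of
    single-copy consensus proteins, computing an outlier-filtered mapping
    depth, and converting depth to genome size through a lineage-calibrated
    Lander-Waterman relation. Includes a built-in seeded translated aligner
    (with an adapter for external blastx-style tools), robust-regression
    calibration of per-lineage slope coefficients, ploidy inference from
    flow-cytometry C-values, and a synthetic-genome simulator used to
    validate every pipeline stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    XVector,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
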