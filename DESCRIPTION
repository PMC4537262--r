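Package: pangenomics
Title: Pan-Genome Accumulation Curves, Openness Fitting, and Comparative
    Genome Statistics
Version: 0.1.0
Authors@R: person("Maintainer", "Anonymous", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative bacterial pan-genomics from ortholog
    presence/absence matrices: parsing of OrthoMCL-style groups files,
    core/moderate/rare partitioning, permutation-based accumulation curves
    for pan-, core- and new-gene counts with exact enumeration at small n,
    Heaps/power-law openness fitting with delete-half jackknife and
    threshold extrapolation, subspecies-specific core-addition statistics
    with exhaustive random-division nulls, four-gamete compatibility scoring
    of binary characters, fragment-based average nucleotide identity (ANIb)
    with identity and coverage filters, glycoside hydrolase family
    profiling (PCA, Kruskal-Wallis), functional-category enrichment across
    pan-genome partitions, and a synthetic-data generator with known ground
    truth for every downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    Biostrings,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
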