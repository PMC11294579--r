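Package: rivermetrix
Title: Molecular River Biomonitoring with Biotic Indices from Metabarcoding Taxa Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for DNA-metabarcoding-based river biomonitoring with benthic
    macroinvertebrates. Converts OTU read tables from bulk-sample and
    environmental DNA (eDNA) surveys into clean presence/absence taxa lists
    (extraction-replicate merging, PCR-replicate consistency filtering,
    negative-control read subtraction), screens taxa lists against invasive
    and protected species checklists, computes the IBMWP biotic index with
    its derived quantities (IASPT, Ecological Quality Ratio, Water Framework
    Directive status class), and provides the statistical toolkit needed to
    compare molecular against morphological monitoring: Spearman correlation,
    regression against the bisector, exact binomial and Friedman paired-status
    tests, Mann-Whitney, Jaccard dissimilarity, and a permutation PERMANOVA
    with marginal term tests. A seeded synthetic-data generator with known
    ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
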