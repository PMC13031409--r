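Package: gtpanel
Title: Design and Power Evaluation of GT-seq SNP Panels for Hybrid
    Detection and Parentage Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building and evaluating targeted amplicon (GT-seq)
    SNP panels for closely related hybridising species. Ranks candidate loci
    by Weir-Cockerham FST and nucleotide diversity, screens multiplex primer
    pools with nearest-neighbour thermodynamics, calls genotypes from
    amplicon allele-read ratios, runs concordance, Hardy-Weinberg and
    missingness quality control, classifies individuals into six
    two-generation hybrid categories with a plug-in likelihood model, and
    quantifies parentage-assignment power through LOD/Delta simulation.
    Includes seeded synthetic-data generators for two-population baselines,
    pedigree hybrid classes and amplicon read counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
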