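Package: SINEBoundary
Title: SINE Insertion Polymorphisms as Mobile Chromatin Boundaries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying young SINE (short interspersed element)
    insertions as mobile boundaries of DNA methylation and histone
    modification domains. Implements strain-pair insertional-polymorphism
    discovery from minimum-gap-penalty pairwise alignments, repeat
    classification against a subfamily consensus library with divergence and
    occupancy statistics, consensus rebuilding and neighbor-joining
    phylogenetics, full-length medium-length-RNA (melRNA-seq) quantification
    with 5.8S rRNA internal-control normalization, CpG-count by methylation
    stratified expression analysis, repeat-density metaprofiles around
    ChIP-seq peak boundaries, and allele-specific boundary-shift analysis in
    F1 hybrids. A seeded synthetic-data generator produces every input the
    pipeline consumes, with ground truth, so all analyses are exercisable and
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Epigenetics, Transposon, Alignment, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
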