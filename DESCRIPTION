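Package: bsamapr
Title: Bulked Segregant Analysis Mapping of Recessive Loci from Pooled
    Allele Depths
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Map-by-sequencing toolkit for monogenic recessive traits in
    biparental F2 populations. Implements chi-square segregation testing,
    QTL-seq style SNP-index and delta SNP-index sliding-window mapping with
    simulation-based null confidence intervals, candidate-region calling,
    marker-based fine mapping with in-silico CAPS digestion and
    co-segregation summaries, coding-indel effect prediction (frameshift,
    premature stop, domain loss), and relative expression by the
    2^-ddCt method. A seeded synthetic-data generator produces F2
    populations, bulk allele-depth tables, marker genotypes, CDS fixtures
    and qPCR Ct tables with the statistical structure the analysis assumes,
    so the full pipeline runs without external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
biocViews: Genetics, VariantDetection, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
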