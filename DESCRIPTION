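Package: chronopop
Title: Clock-Linked Genetic Variation and Migratory Chronotype Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting clock-linked genetic variation
    associated with seasonal migratory timing in wild bird populations. Implements
    a relaxed Weir-Cockerham FST outlier scan between resident and migratory
    groups, SNP genotyping-assay designability filters (GC content, indel and
    flanking-variant proximity, primer uniqueness), ordinal (optimal-scaling)
    principal component analysis of candidate-gene genotypes by alternating
    least squares, passage-date association models with weekly allele-frequency
    trajectories and likelihood-ratio tests, genetic stock identification by an
    EM mixture model over baseline allele-frequency posteriors, and a decision
    procedure distinguishing within-population migratory chronotypes from
    genetically distinct populations passing through at different times.
    Includes seeded synthetic-data generators emulating the statistical
    structure of each pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
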