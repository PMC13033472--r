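Package: cishap
Title: Cis-Haplotype Analysis of Rare and Common Variants at the OCA2 Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Haplotype-based analysis of rare disease variants in the context
    of common pigmentation-trait alleles at the OCA2 locus. Provides a cohort
    data model with summary statistics over proband genotype tables, cis/trans
    phase resolution from family trios and sequencing read fragments, cataloging
    of recurring multi-variant cis-haplotypes anchored on common GWAS alleles,
    weight-matrix splice-site strength scoring with an exhaustive saturation
    screen of splice-window substitutions alone and in cis with an anchor
    allele, a multiplicative allele-dosage expression model, haplotype
    frequency estimation from phased population panels, exon-level copy-number
    calling from SNP-array log R ratios, and seeded synthetic-data generators
    for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
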