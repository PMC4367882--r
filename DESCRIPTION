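Package: snhlmap
Title: Variant Prioritization and Copy Number Association for Hereditary
    Hearing Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-arm analysis pipeline for the genetics of sensorineural
    hearing loss (SNHL). The exome arm prioritizes single-nucleotide and
    indel variants in small pedigrees through a quality / rarity /
    deleteriousness filtering cascade, intersects the outputs of two
    independent variant callers, and applies recessive, compound-
    heterozygous, dominant and de novo segregation models.  The copy-number
    arm scores array-CGH hybridization quality, maps smallest regions of
    overlap of case deletions, and tests genomic regions, genes, pathways
    and overall CNV load for case-control association with Fisher exact
    tests, false-discovery-rate correction and odds ratios.  A compound-
    lesion overlay flags samples carrying both a deletion and a point
    mutation at a configured locus (the DFNB1 pattern).  Synthetic-data
    generators emit pedigree VCFs with planted causal variants, case-
    control CNV cohorts with a planted associated deletion, and Gaussian
    log-R-ratio probe tracks, so every stage can be exercised at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    vcfR,
    igraph,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
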