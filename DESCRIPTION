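Package: breedscope
Title: Pedigree, Runs-of-Homozygosity and Variant-Filtering Analytics for
    Closed Dog Breed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify genetic diversity in closed (pure-bred) dog
    populations from three complementary data sources. From pedigree records
    it computes kinship and inbreeding coefficients by the tabular method,
    mean kinship for breeding management, founder contributions, pedigree
    completeness, popular-sire and demographic statistics, and health-survey
    summaries. From SNP-array genotypes it performs array merging and quality
    control, sliding-window detection of runs of homozygosity (ROH), genomic
    inbreeding (F_ROH), ROH sharing scans, and identity-by-state
    multidimensional scaling. From joint cohort/control whole-genome variant
    tables it applies a filter cascade for private, rare, candidate-gene and
    frequency-enriched variants, and summarises mitochondrial heteroplasmy
    and haplogroup assignments. A synthetic-data generator (bottlenecked
    pedigrees with popular-sire skew, gene-dropped genotypes under a Haldane
    recombination model, planted variant tables and surveys) makes every
    stage testable without access to proprietary registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    VariantAnnotation,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
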