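# small genotype-level variant table: 3 cohort dogs, 4 controls
toyVariantTable <- function() {
  info <- data.frame(id = paste0("v", 1:6), chrom = "1",
                     pos = 1:6 * 100, ref = "A", alt = "T",
                     gene = c("GJA9", "GJA9", NA, "NEFH", "DST", "MME"),
                     consequence = c("missense", "non-coding",
                                     "coding-synonymous", "missense",
                                     "frameshift", "non-coding"))
  cohort <- rbind(v1 = c(1L, 1L, 2L),   # all carriers, controls clean
                  v2 = c(1L, 0L, 0L),   # one carrier, controls clean
                  v3 = c(0L, 0L, 0L),   # absent from cohort
                  v4 = c(2L, 2L, 2L),   # all carriers but also in controls
                  v5 = c(1L, 1L, 1L),   # all carriers, one control carrier
                  v6 = c(0L, 1L, 0L))   # carrier, controls polymorphic
  controls <- rbind(v1 = c(0L, 0L, 0L, 0L),
                    v2 = c(0L, 0L, 0L, 0L),
                    v3 = c(1L, 0L, 0L, 0L),
                    v4 = c(1L, 1L, 0L, 0L),
                    v5 = c(0L, 1L, 0L, 0L),
                    v6 = c(2L, 1L, 1L, 0L))
  makeVariantTable(info, cohort, controls)
}

test_that("allele frequencies are computed over non-missing samples", {
  expect_equal(alleleFrequency(c(rep(1, 9), rep(0, 30))), 9 / 78)
  expect_equal(round(alleleFrequency(c(rep(1, 9), rep(0, 30))), 4), 0.1154)
  expect_equal(round(alleleFrequency(c(1, rep(0, 38))), 4), 0.0128)
  expect_equal(alleleFrequency(c(2, 2, 2)), 1)
  expect_equal(alleleFrequency(c(1, NA, 0)), 0.25)
  expect_error(alleleFrequency(c(NA, NA)), "missing")
  # invariance under reordering and genotype complementation
  withr::with_seed(111, {
    g <- sample(c(0:2, NA), 50, replace = TRUE)
    expect_equal(alleleFrequency(g), alleleFrequency(sample(g)))
    expect_equal(alleleFrequency(g), 1 - alleleFrequency(2 - g))
  })
})

test_that("private filter requires every cohort member as carrier", {
  tbl <- toyVariantTable()
  expect_equal(privateVariantFilter(tbl)$id, "v1")
  # a single missing cohort genotype disqualifies
  info <- data.frame(id = "m1", chrom = "1", pos = 1, ref = "A", alt = "T")
  tblM <- makeVariantTable(info, rbind(c(1L, 1L, NA)),
                           rbind(c(0L, 0L, 0L, 0L)))
  expect_equal(nrow(privateVariantFilter(tblM)), 0L)
})

test_that("rare filter keeps breed-specific alleles incl. private ones", {
  tbl <- toyVariantTable()
  expect_setequal(rareVariantFilter(tbl)$id, c("v1", "v2"))
})

test_that("consequence tally separates coding and protein-changing", {
  tbl <- toyVariantTable()
  ct <- consequenceTally(tbl)
  expect_equal(ct$n_total, 6L)
  expect_equal(ct$n_coding, 4L)           # 2 missense + 1 syn + 1 frameshift
  expect_equal(ct$n_protein_changing, 3L)
  expect_equal(sum(ct$per_class), 6L)
  bad <- tbl
  bad$consequence[1] <- "exotic"
  expect_error(consequenceTally(bad), "exotic")
  empty <- tbl[0, ]
  expect_equal(consequenceTally(empty)$n_total, 0L)
})

test_that("candidate-gene filter is a set intersection", {
  tbl <- toyVariantTable()
  got <- candidateGeneFilter(tbl, c("GJA9", "MME"))
  expect_setequal(got$id, c("v1", "v2", "v6"))
  expect_equal(nrow(candidateGeneFilter(tbl, "ARHGEF10")), 0L)
  expect_error(candidateGeneFilter(tbl, character(0)), "empty")
  # record with no gene annotation is dropped even for wide lists
  expect_false("v3" %in% candidateGeneFilter(tbl, unique(tbl$gene))$id)
})

test_that("enrichment filter applies strict frequency bounds", {
  mk <- function(leo, ctrl)
    data.frame(id = seq_along(leo), gene = "G", aaf_cohort = leo,
               aaf_controls = ctrl)
  expect_equal(nrow(enrichmentFilter(mk(0.5513, 0.0868))), 1L)
  expect_equal(nrow(enrichmentFilter(mk(0.30, 0))), 0L)      # controls at 0
  expect_equal(nrow(enrichmentFilter(mk(0.15, 0.08))), 0L)   # 1.875x <= 2x
  expect_equal(nrow(enrichmentFilter(mk(0.21, 0.10))), 0L)   # controls at cap
  # strictness at the fold boundary
  expect_equal(nrow(enrichmentFilter(mk(0.10, 0.05))), 0L)
  expect_equal(nrow(enrichmentFilter(mk(0.100001, 0.05))), 1L)
})

test_that("the published enriched candidate table passes entirely", {
  tbl <- readVariantTable(system.file("extdata", "enriched_candidates.tsv",
                                      package = "breedscope"),
                          cohortN = 39, controlN = 614)
  kept <- enrichmentFilter(tbl)
  expect_equal(nrow(kept), 22L)
  expect_equal(distinctGeneCount(kept), 17L)
  expect_equal(sum(kept$consequence == "missense"), 21L)
  expect_equal(sum(kept$consequence == "in-frame-del"), 1L)
})

test_that("distinct gene count ignores missing annotations", {
  tbl <- toyVariantTable()
  expect_equal(distinctGeneCount(tbl), 4L)
  expect_equal(distinctGeneCount(tbl[0, ]), 0L)
  one <- tbl; one$gene <- "G"
  expect_equal(distinctGeneCount(one), 1L)
})

test_that("filters are idempotent and rare tables cannot be enriched", {
  tbl <- toyVariantTable()
  r1 <- rareVariantFilter(tbl)
  expect_identical(rareVariantFilter(r1), r1)
  p1 <- privateVariantFilter(tbl)
  expect_identical(privateVariantFilter(p1, cohortN = 3), p1)
  # rare variants have zero control frequency: the strict lower bound of
  # the enrichment filter excludes all of them
  expect_equal(nrow(enrichmentFilter(rareVariantFilter(tbl))), 0L)
})

test_that("planted variant categories are recovered exactly", {
  withr::with_seed(121, {
    for (rep in 1:10) {
      sim <- simulateVariantTable(200, planted = c(private = 7, rare = 13,
                                                   enriched = 9),
                                  seed = sample.int(1e6, 1))
      truth <- split(sim$truth$id, sim$truth$category)
      expect_setequal(privateVariantFilter(sim$table)$id, truth$private)
      expect_setequal(rareVariantFilter(sim$table)$id,
                      c(truth$private, truth$rare))
      expect_setequal(enrichmentFilter(sim$table)$id, truth$enriched)
    }
  })
  # zero planted: all filters empty
  sim0 <- simulateVariantTable(50, planted = c(private = 0), seed = 5)
  expect_equal(nrow(privateVariantFilter(sim0$table)), 0L)
  expect_equal(nrow(rareVariantFilter(sim0$table)), 0L)
  expect_equal(nrow(enrichmentFilter(sim0$table)), 0L)
  # infeasible enrichment request
  expect_error(simulateVariantTable(10, planted = c(enriched = 2),
                                    enrichedControlRange = c(0.05, 0.12)),
               "infeasible")
})

test_that("a multi-sample VCF round-trips into the aggregated table", {
  skip_if_not_installed("VariantAnnotation")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "c1", "c2", "k1", "k2", sep = "\t"),
    paste("1", "100", "v1", "A", "T", ".", ".", "GENE=GJA9;CSQ=missense",
          "GT", "0/1", "1/1", "0/0", "0/0", sep = "\t"),
    paste("1", "200", "v2", "G", "C,A", ".", ".", "GENE=DST;CSQ=missense",
          "GT", "0/1", "0/2", "0/0", "./.", sep = "\t"))
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  tbl <- variantTableFromVcf(f, cohortSamples = c("c1", "c2"),
                             controlSamples = c("k1", "k2"),
                             geneField = "GENE", consequenceField = "CSQ")
  # multiallelic row expands into two biallelic records
  expect_equal(nrow(tbl), 3L)
  v1 <- tbl[tbl$pos == 100, ]
  expect_equal(v1$aaf_cohort, 3 / 4)
  expect_equal(v1$aaf_controls, 0)
  expect_equal(v1$gene, "GJA9")
  expect_equal(privateVariantFilter(tbl)$pos, 100)
  # the G>C allele: one het carrier among the cohort; controls half-called
  v2c <- tbl[tbl$pos == 200 & tbl$alt == "C", ]
  expect_equal(v2c$aaf_cohort, 1 / 4)
  expect_equal(v2c$control_called, 1)
})
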