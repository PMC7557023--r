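# The whole-genome variant filter cascade works on an aggregated variant
# table: one row per biallelic variant with cohort/control frequency and
# carrier summaries plus gene and consequence annotations.  The table can
# be built from per-sample genotypes (makeVariantTable), read pre-aggregated
# from TSV (readVariantTable), or extracted from a multi-sample VCF
# (variantTableFromVcf).

consequenceLevels <- c("coding-synonymous", "missense", "frameshift",
                       "in-frame-ins", "in-frame-del", "nonsense",
                       "non-coding", "other")
codingLevels <- setdiff(consequenceLevels, c("non-coding", "other"))

#' Alternative allele frequency of a genotype vector
#'
#' Alt-allele count divided by twice the number of non-missing diploid
#' samples.  Full precision is kept; round only for presentation.
#'
#' @param genotypes vector of dosages (0, 1, 2, `NA`).
#' @return frequency in `[0, 1]`.
#' @examples
#' alleleFrequency(c(rep(1, 9), rep(0, 30)))  # 9 alt alleles in 39 dogs
#' @export
alleleFrequency <- function(genotypes) {
  ok <- !is.na(genotypes)
  if (!any(ok)) stop("all genotypes are missing")
  sum(genotypes[ok]) / (2 * sum(ok))
}

#' Build an aggregated variant table from genotype matrices
#'
#' @param info data.frame with one row per variant: `chrom`, `pos`, `ref`,
#'   `alt`, and optionally `gene` and `consequence`.
#' @param cohortGeno,controlGeno dosage matrices (variants x samples,
#'   values 0/1/2/`NA`) for the study cohort and the control panel.
#' @return data.frame with the `info` columns plus `aaf_cohort`,
#'   `aaf_controls`, `cohort_alt`, `control_alt`, `cohort_carriers`,
#'   `control_carriers`, `cohort_called`, `control_called`; the declared
#'   panel sizes are kept in attributes `cohort_n` and `control_n`.
#' @export
makeVariantTable <- function(info, cohortGeno, controlGeno) {
  info <- as.data.frame(info)
  stopifnot(nrow(info) == nrow(cohortGeno), nrow(info) == nrow(controlGeno))
  summarise <- function(geno) {
    called <- rowSums(!is.na(geno))
    if (any(called == 0)) stop("variant with all genotypes missing")
    alt <- rowSums(geno, na.rm = TRUE)
    carriers <- rowSums(geno >= 1, na.rm = TRUE)
    data.frame(aaf = alt / (2 * called), alt = alt, carriers = carriers,
               called = called)
  }
  co <- summarise(cohortGeno)
  ct <- summarise(controlGeno)
  if (is.null(info$gene)) info$gene <- NA_character_
  if (is.null(info$consequence)) info$consequence <- NA_character_
  out <- cbind(info,
               data.frame(aaf_cohort = co$aaf, aaf_controls = ct$aaf,
                          cohort_alt = co$alt, control_alt = ct$alt,
                          cohort_carriers = co$carriers,
                          control_carriers = ct$carriers,
                          cohort_called = co$called,
                          control_called = ct$called))
  attr(out, "cohort_n") <- ncol(cohortGeno)
  attr(out, "control_n") <- ncol(controlGeno)
  out
}

#' Read a pre-aggregated variant table
#'
#' Tab-separated, one row per biallelic variant; required columns `chrom`,
#' `pos`, `ref`, `alt`, `aaf_cohort`, `aaf_controls`; optional `gene`,
#' `consequence`, carrier/allele-count columns.  Counts absent from the
#' file are reconstructed from the frequencies and the declared panel
#' sizes (assuming complete calls).
#'
#' @param path TSV path.
#' @param cohortN,controlN declared diploid panel sizes.
#' @return aggregated variant table (see [makeVariantTable()]).
#' @export
readVariantTable <- function(path, cohortN, controlN) {
  x <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                  stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "aaf_cohort", "aaf_controls")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(x$gene)) x$gene <- NA_character_
  if (is.null(x$consequence)) x$consequence <- NA_character_
  if (is.null(x$cohort_called)) x$cohort_called <- cohortN
  if (is.null(x$control_called)) x$control_called <- controlN
  if (is.null(x$cohort_alt))
    x$cohort_alt <- round(x$aaf_cohort * 2 * x$cohort_called)
  if (is.null(x$control_alt))
    x$control_alt <- round(x$aaf_controls * 2 * x$control_called)
  if (is.null(x$cohort_carriers))
    x$cohort_carriers <- pmin(x$cohort_alt, x$cohort_called)
  if (is.null(x$control_carriers))
    x$control_carriers <- pmin(x$control_alt, x$control_called)
  attr(x, "cohort_n") <- cohortN
  attr(x, "control_n") <- controlN
  x
}

#' Build a variant table from a multi-sample VCF
#'
#' Reads a VCF with VariantAnnotation, expands multiallelic records into
#' biallelic ones, converts GT calls to dosages, and aggregates cohort and
#' control panels.  Gene and consequence annotations are taken from the
#' named INFO fields when present.
#'
#' @param vcfPath path to a VCF (may be bgzipped).
#' @param cohortSamples,controlSamples character vectors of sample names.
#' @param geneField,consequenceField INFO field names carrying the
#'   annotations, or `NULL`.
#' @return aggregated variant table (see [makeVariantTable()]).
#' @export
variantTableFromVcf <- function(vcfPath, cohortSamples, controlSamples,
                                geneField = NULL, consequenceField = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("variantTableFromVcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(vcfPath)
  gt <- VariantAnnotation::geno(vcf)$GT
  missS <- setdiff(c(cohortSamples, controlSamples), colnames(gt))
  if (length(missS))
    stop("sample(s) not in VCF: ", paste(missS, collapse = ", "))
  rr <- SummarizedExperiment::rowRanges(vcf)
  alts <- VariantAnnotation::alt(vcf)
  iv <- VariantAnnotation::info(vcf)
  getInfo <- function(field, i) {
    if (is.null(field) || !field %in% names(iv)) return(NA_character_)
    as.character(iv[[field]][i])
  }
  # decompose multiallelic rows: one biallelic record per alt allele,
  # counting only that allele's dosage (any "." makes the call missing)
  parsed <- lapply(seq_len(nrow(gt)), function(i)
    strsplit(gt[i, ], "[/|]"))
  rows <- list()
  dose <- list()
  for (i in seq_along(alts)) {
    for (a in seq_along(alts[[i]])) {
      d <- vapply(parsed[[i]], function(z) {
        if (any(z == ".")) return(NA_integer_)
        sum(as.integer(z) == a)
      }, integer(1))
      names(d) <- colnames(gt)
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = as.character(seqnames(rr))[i], pos = start(rr)[i],
                   ref = as.character(rr$REF[i]),
                   alt = as.character(alts[[i]][a]),
                   gene = getInfo(geneField, i),
                   consequence = getInfo(consequenceField, i))
      dose[[length(dose) + 1L]] <- d
    }
  }
  info <- do.call(rbind, rows)
  dm <- do.call(rbind, dose)
  makeVariantTable(info, dm[, cohortSamples, drop = FALSE],
                   dm[, controlSamples, drop = FALSE])
}

#' Private-variant filter
#'
#' Keeps variants carried by every cohort sample (each with at least one
#' alternative allele; a missing cohort genotype disqualifies the variant)
#' and entirely absent from the controls.
#'
#' @param tbl aggregated variant table.
#' @param cohortN declared cohort size (default: the table attribute).
#' @return the qualifying subset of `tbl`.
#' @export
privateVariantFilter <- function(tbl, cohortN = attr(tbl, "cohort_n")) {
  if (is.null(cohortN)) stop("cohort size unknown; pass cohortN")
  keep <- tbl$cohort_carriers == cohortN & tbl$cohort_called == cohortN &
          tbl$control_alt == 0
  tbl[keep, , drop = FALSE]
}

#' Rare-variant filter
#'
#' Keeps variants with at least one alternative allele in the cohort and
#' none in the controls (breed-specific alleles, including the private
#' ones).
#'
#' @param tbl aggregated variant table.
#' @return the qualifying subset of `tbl`.
#' @export
rareVariantFilter <- function(tbl) {
  tbl[tbl$cohort_alt >= 1 & tbl$control_alt == 0, , drop = FALSE]
}

#' Tally variants by predicted consequence
#'
#' Consequence annotation is consumed, never computed.  Coding classes are
#' synonymous, missense, frameshift, in-frame insertion/deletion and
#' nonsense; protein-changing is coding minus synonymous.
#'
#' @param tbl aggregated variant table with a `consequence` column drawn
#'   from the controlled vocabulary.
#' @return list with `n_total`, `n_coding`, `n_protein_changing` and
#'   `per_class` counts.
#' @export
consequenceTally <- function(tbl) {
  cons <- tbl$consequence
  bad <- setdiff(unique(cons[!is.na(cons)]), consequenceLevels)
  if (length(bad))
    stop("unknown consequence class(es): ", paste(bad, collapse = ", "))
  perClass <- table(factor(cons, levels = consequenceLevels))
  nCoding <- sum(perClass[codingLevels])
  list(n_total = nrow(tbl), n_coding = as.integer(nCoding),
       n_protein_changing =
         as.integer(nCoding - perClass[["coding-synonymous"]]),
       per_class = perClass)
}

#' Read a candidate-gene list
#'
#' TSV with a `gene` column (further columns ignored) or a headerless
#' single-column file.
#'
#' @param path file path.
#' @return character vector of unique gene tokens.
#' @export
readGeneList <- function(path) {
  first <- readLines(path, n = 1)
  hasHeader <- grepl("(^|\t)gene($|\t)", first)
  x <- read.table(path, sep = "\t", header = hasHeader,
                  stringsAsFactors = FALSE, comment.char = "#")
  genes <- if (hasHeader) x$gene else x[[1]]
  unique(genes)
}

#' Candidate-gene filter
#'
#' Keeps variants annotated to a gene in the candidate list; variants
#' without a gene annotation are dropped.
#'
#' @param tbl aggregated variant table.
#' @param genes character vector of gene tokens.
#' @return the qualifying subset of `tbl`.
#' @export
candidateGeneFilter <- function(tbl, genes) {
  if (!length(genes)) stop("empty candidate-gene list")
  tbl[!is.na(tbl$gene) & tbl$gene %in% genes, , drop = FALSE]
}

#' Enrichment filter against the control panel
#'
#' Keeps variants whose control alternative-allele frequency lies strictly
#' between `low` and `high` and whose cohort frequency is strictly more
#' than `fold` times the control frequency.  All comparisons are strict.
#'
#' @param tbl aggregated variant table.
#' @param low,high open control-frequency interval (defaults 0 and 0.10).
#' @param fold minimum cohort/control frequency ratio (exclusive).
#' @return the qualifying subset of `tbl`.
#' @export
enrichmentFilter <- function(tbl, low = 0, high = 0.10, fold = 2) {
  keep <- tbl$aaf_controls > low & tbl$aaf_controls < high &
          tbl$aaf_cohort > fold * tbl$aaf_controls
  tbl[keep, , drop = FALSE]
}

#' Number of distinct annotated genes in a variant table
#'
#' @param tbl aggregated variant table.
#' @return integer count of unique gene tokens (missing annotations are
#'   not counted).
#' @export
distinctGeneCount <- function(tbl) {
  length(unique(tbl$gene[!is.na(tbl$gene)]))
}
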