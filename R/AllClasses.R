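#' Pedigree of a closed population
#'
#' An S4 container for validated pedigree records.  The `records` slot is a
#' data.frame with one row per animal and columns `id`, `sire`, `dam`
#' (character; `NA` = unknown parent), `sex` (`"male"`, `"female"` or `NA`),
#' `birth_date`, `death_date` (`Date` or `NA`), `country` (character or
#' `NA`) and the derived `offspring_count`.  The `topo` slot holds every id
#' exactly once in parents-before-offspring order, which is the order all
#' recursive pedigree computations use.
#'
#' Objects are created by [Pedigree()] or [readPedigree()]; both materialise
#' referenced-but-absent parents as founder records and reject cyclic parent
#' graphs, duplicated ids and sex-inconsistent parent usage.
#'
#' @slot records data.frame of per-animal records (see above).
#' @slot topo character vector, a topological order of the ids.
#' @aliases Pedigree-class
#' @exportClass Pedigree
setClass("Pedigree",
  representation(records = "data.frame", topo = "character"))

setValidity("Pedigree", function(object) {
  rec <- object@records
  msgs <- character()
  need <- c("id", "sire", "dam", "sex", "birth_date", "death_date",
            "country", "offspring_count")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(rec$id)) msgs <- c(msgs, "duplicated ids")
  if (any(!is.na(rec$sire) & rec$sire == rec$id) ||
      any(!is.na(rec$dam) & rec$dam == rec$id))
    msgs <- c(msgs, "an animal cannot be its own parent")
  if (!setequal(object@topo, rec$id) ||
      length(object@topo) != nrow(rec))
    msgs <- c(msgs, "topo must contain every id exactly once")
  # parents must precede offspring in topo order
  pos <- match(rec$id, object@topo)
  sp <- match(rec$sire, object@topo)
  dp <- match(rec$dam, object@topo)
  if (any(sp >= pos, na.rm = TRUE) || any(dp >= pos, na.rm = TRUE))
    msgs <- c(msgs, "topo order is not parents-before-offspring")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Kinship (coancestry) matrix
#'
#' Symmetric matrix of pairwise coancestry coefficients \eqn{f_{ij}} over an
#' ordered set of animals.  The diagonal encodes inbreeding through the
#' identity \eqn{f_{ii} = (1 + F_i)/2}.  Built by [kinshipTabular()].
#'
#' @slot f numeric matrix with identical row/column dimnames (the animal
#'   ids); entries in `[0, 1]`.
#' @aliases KinshipMatrix-class
#' @exportClass KinshipMatrix
setClass("KinshipMatrix", representation(f = "matrix"))

setValidity("KinshipMatrix", function(object) {
  f <- object@f
  if (is.null(dimnames(f)[[1]]) || is.null(dimnames(f)[[2]]))
    return("f must carry animal ids as dimnames")
  if (!identical(rownames(f), colnames(f)))
    return("row and column ids differ")
  if (nrow(f) && max(abs(f - t(f))) > 1e-10)
    return("f is not symmetric")
  if (nrow(f) && (min(f) < -1e-12 || max(f) > 1 + 1e-12))
    return("coancestry coefficients must lie in [0, 1]")
  TRUE
})

#' SNP genotype matrix
#'
#' Biallelic SNP calls for a set of individuals, stored as a
#' [SummarizedExperiment::SummarizedExperiment] with one assay `"calls"`
#' (SNP x individual; values 0 = hom A1, 1 = het, 2 = hom A2, `NA` =
#' missing) and the SNP map in `rowData` (`chrom`, `bp`, `A1`, `A2`;
#' rownames are the SNP ids).  Within each chromosome positions are strictly
#' increasing.  A2 is the counted allele (the minor allele when read from
#' PLINK text files).
#'
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!"calls" %in% assayNames(object)) return("assay 'calls' is required")
  rd <- rowData(object)
  need <- c("chrom", "bp", "A1", "A2")
  if (!all(need %in% names(rd)))
    return(paste("rowData must have columns:", paste(need, collapse = ", ")))
  calls <- assay(object, "calls")
  v <- calls[!is.na(calls)]
  if (length(v) && !all(v %in% c(0L, 1L, 2L)))
    return("calls must be 0, 1, 2 or NA")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("SNP ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    return("individual ids (colnames) must be present and unique")
  # strictly increasing positions within chromosome, in storage order
  sp <- split(rd$bp, as.character(rd$chrom))
  if (any(vapply(sp, function(b) any(diff(b) <= 0), logical(1))))
    return("bp must be strictly increasing within each chromosome")
  TRUE
})

#' Parameters of the sliding-window ROH caller
#'
#' Defaults mirror the conventional sliding-window homozygosity scan of
#' PLINK: 50-SNP windows tolerating at most 1 heterozygous and 5 missing
#' calls, a SNP declared ROH-eligible when at least 5% of the windows
#' covering it are homozygous, and segments retained only when they contain
#' at least `minSnps` SNPs, span at least `minKb` kb, are never interrupted
#' by an inter-SNP gap above `maxGapKb`, and are at least as dense as one
#' SNP per `densityKbPerSnp` kb.  `minSnps = 70` and `densityKbPerSnp = 20`
#' are the values required to keep randomly generated ROH below 5% for a
#' ~130k-SNP array on ~1200 dogs (see [minSnpsForRoh()]).
#'
#' @slot windowSnps integer, SNPs per sliding window.
#' @slot windowHet integer, max heterozygous calls per homozygous window.
#' @slot windowMissing integer, max missing calls per homozygous window.
#' @slot windowHitThreshold numeric in (0, 1], minimum fraction of
#'   homozygous windows covering a SNP for it to be ROH-eligible.
#' @slot minSnps integer, minimum SNPs per retained segment.
#' @slot minKb numeric, minimum segment length in kb.
#' @slot maxGapKb numeric, maximum inter-SNP gap within a segment, kb.
#' @slot densityKbPerSnp numeric, maximum kb per SNP within a segment.
#' @aliases RohParams-class
#' @exportClass RohParams
setClass("RohParams",
  representation(windowSnps = "integer", windowHet = "integer",
                 windowMissing = "integer", windowHitThreshold = "numeric",
                 minSnps = "integer", minKb = "numeric",
                 maxGapKb = "numeric", densityKbPerSnp = "numeric"),
  prototype(windowSnps = 50L, windowHet = 1L, windowMissing = 5L,
            windowHitThreshold = 0.05, minSnps = 70L, minKb = 1000,
            maxGapKb = 1000, densityKbPerSnp = 20))

setValidity("RohParams", function(object) {
  vals <- c(object@windowSnps, object@windowHet + 1L, object@windowMissing + 1L,
            object@minSnps, object@minKb, object@maxGapKb,
            object@densityKbPerSnp)
  if (any(vals <= 0)) return("all parameters must be positive")
  if (object@windowHitThreshold <= 0 || object@windowHitThreshold > 1)
    return("windowHitThreshold must lie in (0, 1]")
  TRUE
})

#' Configuration of the synthetic-data generator
#'
#' Describes the stylised demographic history the generator emulates: a
#' small founder group, a severe mid-century bottleneck, popular-sire skew,
#' large litters, and a SNP panel for gene dropping.  Defaults encode the
#' study conditions of a giant breed formed from 22 founders (10 males,
#' 12 females) that passed a 1946 bottleneck of 17 dogs, with mean litter
#' size 6.5 and a ~4-year generation interval; see [simConfig()].
#'
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
  representation(seed = "integer",
                 nFounderMales = "integer", nFounderFemales = "integer",
                 startYear = "integer", nYears = "integer",
                 bottleneckYear = "integer", bottleneckSurvivors = "integer",
                 sireSkew = "numeric", litterMean = "numeric",
                 littersPerYear = "integer",
                 matingMinAge = "integer", matingMaxAge = "integer",
                 lifespanMean = "numeric", lifespanSd = "numeric",
                 nSnps = "integer", chromLengthsMb = "numeric",
                 cmPerMb = "numeric", freqBeta = "numeric"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (object@nFounderMales < 1L || object@nFounderFemales < 1L)
    msgs <- c(msgs, "at least one founder of each sex is required")
  if (object@nYears < 1L) msgs <- c(msgs, "nYears must be positive")
  if (object@bottleneckYear < object@startYear ||
      object@bottleneckYear >= object@startYear + object@nYears)
    msgs <- c(msgs, "bottleneckYear must fall within the simulated range")
  if (object@bottleneckSurvivors < 2L)
    msgs <- c(msgs, "bottleneckSurvivors must be at least 2")
  if (object@litterMean <= 0) msgs <- c(msgs, "litterMean must be positive")
  if (object@littersPerYear < 1L)
    msgs <- c(msgs, "littersPerYear must be positive")
  if (object@matingMinAge < 1L || object@matingMaxAge < object@matingMinAge)
    msgs <- c(msgs, "mating ages must satisfy 1 <= min <= max")
  if (object@lifespanMean <= 0 || object@lifespanSd <= 0)
    msgs <- c(msgs, "lifespan parameters must be positive")
  if (object@nSnps < 1L || any(object@chromLengthsMb <= 0))
    msgs <- c(msgs, "SNP panel must have positive size and lengths")
  if (object@cmPerMb <= 0) msgs <- c(msgs, "cmPerMb must be positive")
  if (length(object@freqBeta) != 2L || any(object@freqBeta <= 0))
    msgs <- c(msgs, "freqBeta must be two positive shape parameters")
  if (object@sireSkew < 0) msgs <- c(msgs, "sireSkew must be >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
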