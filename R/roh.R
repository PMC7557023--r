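#' @rdname RohParams-class
#' @param windowSnps,windowHet,windowMissing,windowHitThreshold,minSnps,minKb,maxGapKb,densityKbPerSnp
#'   see the class slots.
#' @export
RohParams <- function(windowSnps = 50, windowHet = 1, windowMissing = 5,
                      windowHitThreshold = 0.05, minSnps = 70, minKb = 1000,
                      maxGapKb = 1000, densityKbPerSnp = 20) {
  new("RohParams", windowSnps = as.integer(windowSnps),
      windowHet = as.integer(windowHet),
      windowMissing = as.integer(windowMissing),
      windowHitThreshold = windowHitThreshold,
      minSnps = as.integer(minSnps), minKb = minKb, maxGapKb = maxGapKb,
      densityKbPerSnp = densityKbPerSnp)
}

setMethod("show", "RohParams", function(object) {
  cat("RohParams: window", object@windowSnps, "SNPs (<=", object@windowHet,
      "het, <=", object@windowMissing, "missing), hit threshold",
      object@windowHitThreshold, "\n  segment: >=", object@minSnps,
      "SNPs, >=", object@minKb, "kb, gap <=", object@maxGapKb,
      "kb, density <=", object@densityKbPerSnp, "kb/SNP\n")
})

#' Detect runs of homozygosity by a sliding-window scan
#'
#' For each individual and chromosome, windows of `windowSnps` consecutive
#' SNPs are classified homozygous when they contain at most `windowHet`
#' heterozygous and at most `windowMissing` missing calls.  Each SNP's hit
#' rate is the fraction of windows covering it that are homozygous; SNPs
#' with a hit rate of at least `windowHitThreshold` are ROH-eligible.
#' Maximal stretches of consecutive eligible SNPs form candidate segments,
#' split wherever two adjacent SNPs are more than `maxGapKb` kb apart, and
#' are retained when they contain at least `minSnps` SNPs, span at least
#' `minKb` kb and have at most `densityKbPerSnp` kb per SNP.
#'
#' @param g a QC'd [GenotypeMatrix-class] (map sorted by position).
#' @param params a [RohParams-class] object.
#' @return A [GenomicRanges::GRanges] with one range per segment
#'   (`seqnames` = chromosome, start/end = first/last SNP position) and
#'   metadata columns `individual`, `n_snps`, `length_kb`.
#' @export
callRoh <- function(g, params = RohParams()) {
  map <- snpMap(g)
  calls <- genotypeCalls(g)
  if (any(vapply(split(map$bp, map$chrom), function(b) any(diff(b) <= 0),
                 logical(1))))
    stop("SNP map must be sorted with strictly increasing positions")
  w <- params@windowSnps
  segs <- list()
  byChrom <- split(seq_len(nrow(map)), map$chrom)
  for (ind in colnames(g)) {
    gi <- calls[, ind]
    for (chrom in names(byChrom)) {
      idx <- byChrom[[chrom]]
      m <- length(idx)
      nwin <- m - w + 1L
      if (nwin < 1L) next
      x <- gi[idx]
      bp <- map$bp[idx]
      het <- as.integer(!is.na(x) & x == 1L)
      mis <- as.integer(is.na(x))
      cumHet <- c(0L, cumsum(het))
      cumMis <- c(0L, cumsum(mis))
      k <- seq_len(nwin)
      winHom <- (cumHet[k + w] - cumHet[k]) <= params@windowHet &
                (cumMis[k + w] - cumMis[k]) <= params@windowMissing
      cumHom <- c(0L, cumsum(as.integer(winHom)))
      i <- seq_len(m)
      lo <- pmax(1L, i - w + 1L)
      hi <- pmin(i, nwin)
      tot <- hi - lo + 1L
      hom <- cumHom[hi + 1L] - cumHom[lo]
      eligible <- tot > 0L & (hom / pmax(tot, 1L)) >= params@windowHitThreshold
      if (!any(eligible)) next
      # runs of consecutive eligible SNPs, split at large physical gaps
      brk <- c(TRUE, diff(i[eligible]) != 1L |
                     diff(bp[eligible]) > params@maxGapKb * 1000)
      runId <- cumsum(brk)
      for (r in split(which(eligible), runId)) {
        nS <- length(r)
        lenKb <- (bp[r[nS]] - bp[r[1]] + 1) / 1000
        if (nS >= params@minSnps && lenKb >= params@minKb &&
            lenKb / nS <= params@densityKbPerSnp) {
          segs[[length(segs) + 1L]] <-
            data.frame(individual = ind, chrom = chrom,
                       start = bp[r[1]], end = bp[r[nS]],
                       n_snps = nS, length_kb = lenKb)
        }
      }
    }
  }
  if (!length(segs)) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(individual = character(),
                                      n_snps = integer(),
                                      length_kb = numeric())
    return(gr)
  }
  df <- do.call(rbind, segs)
  GRanges(seqnames = df$chrom, ranges = IRanges(df$start, df$end),
          individual = df$individual, n_snps = as.integer(df$n_snps),
          length_kb = df$length_kb)
}

#' Autosomal genome span covered by the SNP panel
#'
#' Sum over autosomes of the distance from the first to the last retained
#' SNP (inclusive), in kb: the denominator of [fRoh()].
#'
#' @param g a [GenotypeMatrix-class].
#' @param autosomes chromosome labels counted as autosomes.
#' @return covered span in kb.
#' @export
coveredAutosomeKb <- function(g, autosomes = as.character(1:38)) {
  map <- snpMap(g)
  map <- map[isAutosome(map$chrom, autosomes), ]
  if (!nrow(map)) stop("no autosomal SNPs in the panel")
  sum(vapply(split(map$bp, map$chrom),
             function(b) (max(b) - min(b) + 1) / 1000, numeric(1)))
}

#' Genomic inbreeding coefficient from ROH (F_ROH)
#'
#' Total ROH length of an individual divided by the SNP-covered autosomal
#' genome length.
#'
#' @param segments ROH segments as returned by [callRoh()].
#' @param coveredKb covered autosomal span in kb (see [coveredAutosomeKb()]).
#' @param individuals ids to report (default: those with segments);
#'   individuals without segments get 0.
#' @return named numeric vector of F_ROH values in `[0, 1]`.
#' @export
fRoh <- function(segments, coveredKb, individuals = NULL) {
  if (coveredKb <= 0) stop("coveredKb must be positive")
  ind <- mcols(segments)$individual
  if (is.null(individuals)) individuals <- unique(ind)
  tot <- tapply(mcols(segments)$length_kb, ind, sum)
  out <- setNames(rep(0, length(individuals)), individuals)
  hit <- intersect(individuals, names(tot))
  out[hit] <- tot[hit] / coveredKb
  out
}

#' Tabulate ROH by length class
#'
#' Bins segment lengths into the standard classes (default edges 1, 2, 4,
#' 8, 10 Mb and above), whose balance separates ancient inbreeding (many
#' short ROH) from recent inbreeding (long ROH).
#'
#' @param segments ROH segments ([callRoh()]).
#' @param binEdgesMb increasing lower bin edges in Mb; the last class is
#'   open-ended.
#' @return data.frame with `class`, `n`, `frequency` (sums to 1).
#' @export
rohLengthClasses <- function(segments, binEdgesMb = c(1, 2, 4, 8, 10)) {
  if (!length(segments)) stop("no ROH segments")
  mb <- mcols(segments)$length_kb / 1000
  edges <- c(binEdgesMb, Inf)
  labs <- paste0("[", edges[-length(edges)], ",",
                 ifelse(is.finite(edges[-1]), edges[-1], "Inf"), ")")
  cls <- cut(mb, breaks = edges, right = FALSE, labels = labs)
  n <- as.integer(table(cls))
  data.frame(class = labs, n = n, frequency = n / length(mb))
}

#' Per-chromosome ROH summary
#'
#' For each chromosome of the map: the number of segments and the mean,
#' over all individuals, of the fraction of the chromosome's covered span
#' that lies in a ROH.
#'
#' @param segments ROH segments ([callRoh()]).
#' @param g the [GenotypeMatrix-class] the segments were called on.
#' @return data.frame with `chrom`, `n_roh`, `mean_fraction_in_roh`.
#' @export
perChromosomeSummary <- function(segments, g) {
  map <- snpMap(g)
  nInd <- ncol(g)
  chroms <- unique(map$chrom)
  segChrom <- as.character(seqnames(segments))
  out <- lapply(chroms, function(ch) {
    b <- map$bp[map$chrom == ch]
    span <- max(b) - min(b) + 1
    sel <- segChrom == ch
    bpByInd <- tapply(width(segments)[sel], mcols(segments)$individual[sel],
                      sum)
    frac <- sum(bpByInd) / (span * nInd)  # individuals without ROH count 0
    data.frame(chrom = ch, n_roh = sum(sel), mean_fraction_in_roh = frac)
  })
  do.call(rbind, out)
}

#' ROH sharing scan across the genome
#'
#' For every SNP of the map, the fraction of individuals having at least
#' one ROH segment containing that SNP; regions where this fraction is
#' high are candidate breed-defining (or selection) regions.  When
#' `threshold` is given, maximal runs of consecutive SNPs with a sharing
#' fraction strictly above it are also returned as intervals.
#'
#' @param segments ROH segments ([callRoh()]).
#' @param g the [GenotypeMatrix-class] the segments were called on.
#' @param threshold optional sharing fraction for the interval query.
#' @return list with `per_snp` (data.frame `chrom`, `bp`, `fraction`) and
#'   `intervals` (a [GenomicRanges::GRanges], empty when no threshold).
#' @export
rohSharingScan <- function(segments, g, threshold = NULL) {
  map <- snpMap(g)
  nInd <- ncol(g)
  count <- integer(nrow(map))
  segChrom <- as.character(seqnames(segments))
  for (ch in unique(segChrom)) {
    rows <- which(map$chrom == ch)
    bp <- map$bp[rows]
    sel <- which(segChrom == ch)
    # segments of one individual do not overlap, so plain accumulation
    # counts each individual at most once per SNP
    lo <- findInterval(start(segments)[sel] - 1L, bp) + 1L
    hi <- findInterval(end(segments)[sel], bp)
    d <- integer(length(rows) + 1L)
    ok <- lo <= hi
    for (s in which(ok)) {
      d[lo[s]] <- d[lo[s]] + 1L
      d[hi[s] + 1L] <- d[hi[s] + 1L] - 1L
    }
    count[rows] <- cumsum(d[-length(d)])
  }
  perSnp <- data.frame(chrom = map$chrom, bp = map$bp,
                       fraction = count / nInd)
  intervals <- GRanges()
  if (!is.null(threshold)) {
    hits <- perSnp$fraction > threshold
    if (any(hits)) {
      grs <- lapply(unique(map$chrom[hits]), function(ch) {
        rows <- which(map$chrom == ch)
        h <- hits[rows]
        r <- rle(h)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$values
        GRanges(seqnames = ch,
                ranges = IRanges(map$bp[rows[starts[keep]]],
                                 map$bp[rows[ends[keep]]]))
      })
      intervals <- do.call(c, grs)
    }
  }
  list(per_snp = perSnp, intervals = intervals)
}
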