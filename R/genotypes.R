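#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix of allele-2 dosages (0, 1, 2, `NA`), SNPs in
#'   rows and individuals in columns.  Row order need not be sorted; SNPs
#'   are re-ordered by (chromosome, position).
#' @param map data.frame with one row per SNP: `chrom`, `bp`, `id`
#'   (optional; defaults to `chrom:bp`), `A1`, `A2`.
#' @param individuals optional individual ids (default: `colnames(calls)`).
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(calls, map, individuals = colnames(calls)) {
  calls <- as.matrix(calls)
  mode(calls) <- "integer"
  map <- as.data.frame(map)
  if (nrow(map) != nrow(calls))
    stop("map and calls disagree on the number of SNPs")
  if (is.null(map$id)) map$id <- paste0(map$chrom, ":", map$bp)
  if (anyDuplicated(map$id))
    stop("duplicated SNP id(s): ",
         paste(unique(map$id[duplicated(map$id)]), collapse = ", "))
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(ncol(calls)))
  num <- suppressWarnings(as.integer(as.character(map$chrom)))
  o <- order(is.na(num), num, as.character(map$chrom), map$bp)
  map <- map[o, , drop = FALSE]
  calls <- calls[o, , drop = FALSE]
  dup <- duplicated(paste(map$chrom, map$bp))
  if (any(dup))
    stop("duplicated chrom:bp position(s): ",
         paste(paste0(map$chrom, ":", map$bp)[dup], collapse = ", "))
  rd <- S4Vectors::DataFrame(chrom = as.character(map$chrom),
                             bp = as.integer(map$bp),
                             A1 = as.character(map$A1),
                             A2 = as.character(map$A2),
                             row.names = map$id)
  se <- SummarizedExperiment(assays = list(calls = calls), rowData = rd)
  rownames(se) <- map$id
  colnames(se) <- individuals
  new("GenotypeMatrix", se)
}

#' @describeIn GenotypeMatrix the SNP map as a data.frame
#'   (`id`, `chrom`, `bp`, `A1`, `A2`), in storage order.
#' @param g a [GenotypeMatrix-class].
#' @export
snpMap <- function(g) {
  rd <- rowData(g)
  data.frame(id = rownames(g), chrom = rd$chrom, bp = rd$bp,
             A1 = rd$A1, A2 = rd$A2, stringsAsFactors = FALSE)
}

#' @describeIn GenotypeMatrix the dosage matrix (SNP x individual).
#' @export
genotypeCalls <- function(g) assay(g, "calls")

#' Read PLINK text PED/MAP genotype files
#'
#' Parses the whitespace-separated text formats: the MAP file gives one SNP
#' per line (`chrom id cM bp`), the PED file one individual per line with
#' six leading columns (`FID IID PAT MAT SEX PHENO`) followed by two allele
#' columns per SNP, `0` marking a missing allele.  Allele coding is
#' normalised so that A2, the counted allele, is the minor allele; sites
#' with more than two observed alleles raise an error naming the SNP, as do
#' ragged rows.
#'
#' @param pedPath,mapPath paths to the .ped and .map files.
#' @return A [GenotypeMatrix-class].
#' @export
readPlinkText <- function(pedPath, mapPath) {
  mp <- read.table(mapPath, header = FALSE, colClasses = "character")
  if (ncol(mp) < 4) stop("MAP file must have 4 columns")
  map <- data.frame(chrom = mp[[1]], id = mp[[2]], bp = as.integer(mp[[4]]),
                    stringsAsFactors = FALSE)
  m <- nrow(map)
  lines <- readLines(pedPath)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nTok <- lengths(toks)
  if (any(nTok != 6 + 2 * m))
    stop("ragged PED row(s) at line(s): ",
         paste(which(nTok != 6 + 2 * m), collapse = ", "),
         " (expected ", 6 + 2 * m, " fields)")
  ids <- vapply(toks, `[`, character(1), 2L)
  alleles <- do.call(cbind, lapply(toks, function(t) t[-(1:6)]))
  # alleles: 2m x n; rows 2k-1, 2k belong to SNP k
  a1 <- alleles[seq(1, 2 * m - 1, by = 2), , drop = FALSE]
  a2 <- alleles[seq(2, 2 * m, by = 2), , drop = FALSE]
  halfMissing <- xor(a1 == "0", a2 == "0")
  if (any(halfMissing))
    stop("half-missing genotype(s) at SNP(s): ",
         paste(unique(map$id[which(halfMissing, arr.ind = TRUE)[, 1]]),
               collapse = ", "))
  calls <- matrix(NA_integer_, m, length(ids))
  A1 <- A2 <- character(m)
  for (k in seq_len(m)) {
    x <- c(a1[k, ], a2[k, ])
    obs <- x[x != "0"]
    all_ <- sort(unique(obs))
    if (length(all_) > 2)
      stop("more than two alleles at SNP ", map$id[k], ": ",
           paste(all_, collapse = "/"))
    if (length(all_) == 0) { A1[k] <- "0"; A2[k] <- "0"; next }
    if (length(all_) == 1) {
      A1[k] <- all_; A2[k] <- "0"
      calls[k, a1[k, ] != "0"] <- 0L
      next
    }
    cnt <- table(factor(obs, levels = all_))
    # minor allele counted; ties broken alphabetically (second allele)
    minor <- if (cnt[[1]] < cnt[[2]]) all_[1] else all_[2]
    major <- setdiff(all_, minor)
    A1[k] <- major; A2[k] <- minor
    nonmiss <- a1[k, ] != "0"
    calls[k, nonmiss] <- (a1[k, nonmiss] == minor) + (a2[k, nonmiss] == minor)
  }
  GenotypeMatrix(calls, data.frame(chrom = map$chrom, bp = map$bp,
                                   id = map$id, A1 = A1, A2 = A2),
                 individuals = ids)
}

complementAllele <- function(a) {
  unname(c(A = "T", T = "A", C = "G", G = "C", `0` = "0")[a])
}

isAmbiguousPair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

minorFreq <- function(callsRow) {
  x <- callsRow[!is.na(callsRow)]
  if (!length(x)) return(NA_real_)
  p <- sum(x) / (2 * length(x))
  min(p, 1 - p)
}

#' Merge two SNP-array genotype sets
#'
#' Restricts to SNPs present (by chromosome and position) on both arrays,
#' reconciles allele coding (including strand flips for unambiguous allele
#' pairs), and drops (i) SNPs whose alleles cannot be reconciled,
#' (ii) strand-ambiguous A/T and C/G SNPs whose minor-allele frequency
#' exceeds `ambiguousMaf` on either array (strand is then unresolvable),
#' and (iii) SNPs whose post-merge missingness is `maxMissing` or higher
#' (strictly lower passes).  Individual sets must be disjoint.
#'
#' @param a,b [GenotypeMatrix-class] objects.
#' @param maxMissing exclusive post-merge missingness bound (default 0.1).
#' @param ambiguousMaf MAF above which ambiguous-strand SNPs are dropped.
#' @return A [GenotypeMatrix-class] of the merged individuals; the
#'   attrition per criterion is in `metadata(x)$merge_attrition`.
#' @export
mergeArrays <- function(a, b, maxMissing = 0.1, ambiguousMaf = 0.4) {
  if (length(intersect(colnames(a), colnames(b))))
    stop("individual sets must be disjoint")
  ma <- snpMap(a); mb <- snpMap(b)
  keyA <- paste(ma$chrom, ma$bp)
  keyB <- paste(mb$chrom, mb$bp)
  shared <- intersect(keyA, keyB)
  if (!length(shared)) stop("no overlapping SNPs between the two arrays")
  ia <- match(shared, keyA); ib <- match(shared, keyB)
  ca <- genotypeCalls(a)[ia, , drop = FALSE]
  cb <- genotypeCalls(b)[ib, , drop = FALSE]
  A1a <- ma$A1[ia]; A2a <- ma$A2[ia]
  A1b <- mb$A1[ib]; A2b <- mb$A2[ib]
  n <- length(shared)
  keep <- rep(TRUE, n)
  nAmbig <- nConflict <- 0L
  for (k in seq_len(n)) {
    pa <- c(A1a[k], A2a[k]); pb <- c(A1b[k], A2b[k])
    if (any(pa == "0") || any(pb == "0")) { # monomorphic on one array
      known <- setdiff(c(pa, pb), "0")
      if (length(unique(known)) <= 2 &&
          all(setdiff(pb, "0") %in% c(pa, complementAllele(pa)))) {
        # align a monomorphic side to the polymorphic one; b counted allele
        if (!any(pb == "0") && !setequal(pb, pa)) pb <- complementAllele(pb)
        if (!any(pb == "0") && pb[2] != pa[2] && pa[2] != "0")
          cb[k, ] <- 2L - cb[k, ]
        next
      }
      keep[k] <- FALSE; nConflict <- nConflict + 1L; next
    }
    ambig <- isAmbiguousPair(pa[1], pa[2]) || isAmbiguousPair(pb[1], pb[2])
    if (ambig) {
      mafs <- c(minorFreq(ca[k, ]), minorFreq(cb[k, ]))
      if (any(mafs > ambiguousMaf, na.rm = TRUE)) {
        keep[k] <- FALSE; nAmbig <- nAmbig + 1L; next
      }
      if (!setequal(pa, pb)) {
        keep[k] <- FALSE; nConflict <- nConflict + 1L; next
      }
      if (pb[2] != pa[2]) cb[k, ] <- 2L - cb[k, ]
      next
    }
    if (setequal(pa, pb)) {
      if (pb[2] != pa[2]) cb[k, ] <- 2L - cb[k, ]
    } else if (setequal(pa, complementAllele(pb))) {
      pbf <- complementAllele(pb)
      if (pbf[2] != pa[2]) cb[k, ] <- 2L - cb[k, ]
    } else {
      keep[k] <- FALSE; nConflict <- nConflict + 1L
    }
  }
  calls <- cbind(ca, cb)[keep, , drop = FALSE]
  miss <- rowMeans(is.na(calls))
  passMiss <- miss < maxMissing
  attrition <- c(not_shared = length(keyA) - n, allele_conflict = nConflict,
                 ambiguous_strand = nAmbig,
                 missingness = sum(!passMiss))
  calls <- calls[passMiss, , drop = FALSE]
  idx <- ia[keep][passMiss]
  if (!nrow(calls))
    stop("no SNPs survive the merge (attrition: ",
         paste(names(attrition), attrition, sep = "=", collapse = ", "), ")")
  out <- GenotypeMatrix(calls,
                        data.frame(chrom = ma$chrom[idx], bp = ma$bp[idx],
                                   id = ma$id[idx], A1 = ma$A1[idx],
                                   A2 = ma$A2[idx]),
                        individuals = c(colnames(a), colnames(b)))
  metadata(out)$merge_attrition <- attrition
  out
}
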