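#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test: given the observed allele counts, the
#' probability of each possible heterozygote count is computed under random
#' union of gametes, and the p-value is the sum of the probabilities of all
#' configurations no more probable than the observed one.  A monomorphic
#' site has a single configuration and p = 1.  Probabilities are evaluated
#' by the stable ratio recurrence
#' \eqn{P(h+2)/P(h) = 4 r_h c_h / ((h+1)(h+2))}, where \eqn{r_h} and
#' \eqn{c_h} are the rare- and common-homozygote counts at heterozygote
#' count \eqn{h}.
#'
#' @param nAA,nAa,naa non-negative genotype counts (common homozygote,
#'   heterozygote, rare homozygote; the labelling is immaterial).
#' @return the exact two-sided p-value.
#' @examples
#' hweExactTest(25, 50, 25)
#' hweExactTest(0, 100, 0) < 1e-10
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  counts <- c(nAA, nAa, naa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped individual is required")
  rare <- min(2 * nAA + nAa, 2 * naa + nAa)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  logp <- numeric(length(hs))
  for (k in seq_along(hs)[-1]) {
    h <- hs[k - 1]
    rh <- (rare - h) / 2
    ch <- n - h - rh  # common homozygotes at het count h
    logp[k] <- logp[k - 1] + log(4 * rh * ch) - log((h + 1) * (h + 2))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(nAa, hs)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

#' Quality-control filter for ROH analyses
#'
#' Retains only biallelic SNPs (both alleles observed) on the autosomes and
#' removes SNPs deviating from Hardy-Weinberg equilibrium at `hweAlpha`
#' (strictly `p < hweAlpha` is removed).  The removal count per criterion
#' is attached as `metadata(x)$qc_attrition`.
#'
#' @param g a [GenotypeMatrix-class].
#' @param hweAlpha exact-test significance bound (default 1e-4).
#' @param autosomes chromosome labels counted as autosomes (default 1-38,
#'   the canine complement).
#' @return the filtered [GenotypeMatrix-class].
#' @export
qcFilter <- function(g, hweAlpha = 1e-4, autosomes = as.character(1:38)) {
  map <- snpMap(g)
  calls <- genotypeCalls(g)
  auto <- isAutosome(map$chrom, autosomes)
  biall <- map$A1 != "0" & map$A2 != "0" & !is.na(map$A1) & !is.na(map$A2)
  hweP <- rep(NA_real_, nrow(map))
  cand <- which(auto & biall)
  for (k in cand) {
    x <- calls[k, ]
    hweP[k] <- hweExactTest(sum(x == 0L, na.rm = TRUE),
                            sum(x == 1L, na.rm = TRUE),
                            sum(x == 2L, na.rm = TRUE))
  }
  hweOk <- !is.na(hweP) & hweP >= hweAlpha
  keep <- auto & biall & hweOk
  attrition <- c(non_autosomal = sum(!auto),
                 not_biallelic = sum(auto & !biall),
                 hwe = sum(auto & biall & !hweOk))
  if (!any(keep))
    stop("no SNPs pass QC (attrition: ",
         paste(names(attrition), attrition, sep = "=", collapse = ", "), ")")
  out <- GenotypeMatrix(calls[keep, , drop = FALSE], map[keep, , drop = FALSE],
                        individuals = colnames(g))
  metadata(out)$qc_attrition <- attrition
  out
}

#' Minimum number of SNPs for a reliable ROH call
#'
#' Number of consecutive homozygous SNPs needed so that fewer than a
#' fraction `alpha` of ROH arise by chance across the whole dataset,
#' following the standard multiple-testing argument: the expected number of
#' chance runs of length l over `nSnps` x `nIndividuals` tests is below
#' `alpha` once \eqn{(1 - het)^l < alpha / (nSnps \cdot nIndividuals)}.
#'
#' @param nSnps number of SNPs in the panel.
#' @param nIndividuals number of genotyped individuals.
#' @param hetMean mean SNP heterozygosity across individuals, in (0, 1).
#' @param alpha tolerated fraction of chance ROH (default 0.05).
#' @return integer minimum SNP count,
#'   \eqn{\lceil \ln(\alpha/(n_s n_i)) / \ln(1 - het) \rceil}.
#' @examples
#' minSnpsForRoh(132711, 1203, hetMean = 0.27)  # 70
#' @export
minSnpsForRoh <- function(nSnps, nIndividuals, hetMean, alpha = 0.05) {
  if (nSnps < 1 || nIndividuals < 1) stop("nSnps and nIndividuals must be >= 1")
  if (hetMean <= 0 || hetMean >= 1) stop("hetMean must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  as.integer(ceiling(log(alpha / (nSnps * nIndividuals)) / log(1 - hetMean)))
}
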