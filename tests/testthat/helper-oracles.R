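# Independent oracles used to check the package implementations.
# These are deliberately naive (enumeration / literal definitions) and
# share no code with the functions they validate.

# ---- path-counting kinship oracle -------------------------------------
# f_ij = sum over common ancestors A and pairs of ancestral paths that
# share only A of (1/2)^(L1 + L2 + 1) * (1 + F_A).

# all ancestral paths from x upward, each a vector of ids (x first)
allPathsUp <- function(rec, x) {
  row <- match(x, rec$id)
  out <- list(x)
  for (p in c(rec$sire[row], rec$dam[row])) {
    if (!is.na(p)) {
      for (sub in allPathsUp(rec, p)) out <- c(out, list(c(x, sub)))
    }
  }
  out
}

oracleCoancestry <- function(rec, a, b, memoF = new.env()) {
  if (a == b) return(0.5 * (1 + oracleF(rec, a, memoF)))
  pa <- allPathsUp(rec, a)
  pb <- allPathsUp(rec, b)
  total <- 0
  for (p1 in pa) {
    anc <- p1[length(p1)]
    for (p2 in pb) {
      if (p2[length(p2)] != anc) next
      # paths must be disjoint except for the common ancestor
      if (length(intersect(p1[-length(p1)], p2[-length(p2)]))) next
      L1 <- length(p1) - 1
      L2 <- length(p2) - 1
      total <- total + 0.5^(L1 + L2 + 1) * (1 + oracleF(rec, anc, memoF))
    }
  }
  total
}

oracleF <- function(rec, x, memoF = new.env()) {
  if (!is.null(memoF[[x]])) return(memoF[[x]])
  row <- match(x, rec$id)
  s <- rec$sire[row]; d <- rec$dam[row]
  val <- if (is.na(s) || is.na(d)) 0 else oracleCoancestry(rec, s, d, memoF)
  memoF[[x]] <- val
  val
}

oracleKinshipMatrix <- function(rec, ids = rec$id) {
  memoF <- new.env()
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq(i, n)) {
    K[i, j] <- K[j, i] <- oracleCoancestry(rec, ids[i], ids[j], memoF)
  }
  K
}

# ---- random pedigree generator (sex-consistent DAG) -------------------
randomPedigree <- function(n = 30, nFounders = 8, pUnknown = 0.2) {
  id <- sprintf("A%02d", seq_len(n))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  sex[1:2] <- c("male", "female")  # both sexes available
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i <= nFounders) next
    males <- id[seq_len(i - 1)][sex[seq_len(i - 1)] == "male"]
    females <- id[seq_len(i - 1)][sex[seq_len(i - 1)] == "female"]
    if (length(males) && runif(1) > pUnknown) sire[i] <- sample(males, 1)
    if (length(females) && runif(1) > pUnknown) dam[i] <- sample(females, 1)
  }
  data.frame(id = id, sire = sire, dam = dam, sex = sex,
             stringsAsFactors = FALSE)
}

# ---- HWE exact enumeration oracle -------------------------------------
# direct log-factorial evaluation of the conditional distribution of the
# heterozygote count given the allele counts
oracleHweP <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  rare <- min(nA, na)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hs, function(h) {
    r <- (rare - h) / 2
    c_ <- (max(nA, na) - h) / 2
    lgamma(n + 1) - lgamma(r + 1) - lgamma(h + 1) - lgamma(c_ + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[match(nAa, hs)]
  sum(p[p <= obs * (1 + 1e-10)])
}

# ---- brute-force ROH window oracle ------------------------------------
# literal re-statement of the sliding-window definition with plain loops
oracleRohOneChrom <- function(calls, bp, params) {
  m <- length(calls)
  w <- params@windowSnps
  nwin <- m - w + 1
  eligible <- rep(FALSE, m)
  if (nwin >= 1) {
    winHom <- logical(nwin)
    for (k in seq_len(nwin)) {
      win <- calls[k:(k + w - 1)]
      winHom[k] <- sum(win == 1, na.rm = TRUE) <= params@windowHet &&
                   sum(is.na(win)) <= params@windowMissing
    }
    for (i in seq_len(m)) {
      ks <- intersect(seq_len(nwin), (i - w + 1):i)
      if (!length(ks)) next
      eligible[i] <- mean(winHom[ks]) >= params@windowHitThreshold
    }
  }
  segs <- list()
  run <- integer(0)
  flush <- function(run, segs) {
    if (!length(run)) return(segs)
    nS <- length(run)
    lenKb <- (bp[run[nS]] - bp[run[1]] + 1) / 1000
    if (nS >= params@minSnps && lenKb >= params@minKb &&
        lenKb / nS <= params@densityKbPerSnp)
      segs[[length(segs) + 1]] <- c(start = bp[run[1]], end = bp[run[nS]],
                                    n = nS)
    segs
  }
  for (i in seq_len(m)) {
    if (eligible[i]) {
      if (length(run) &&
          (bp[i] - bp[run[length(run)]] > params@maxGapKb * 1000)) {
        segs <- flush(run, segs)
        run <- integer(0)
      }
      run <- c(run, i)
    } else {
      segs <- flush(run, segs)
      run <- integer(0)
    }
  }
  segs <- flush(run, segs)
  if (!length(segs)) return(data.frame(start = numeric(), end = numeric(),
                                       n = numeric()))
  as.data.frame(do.call(rbind, segs))
}

# ---- Monte-Carlo gene-dropping oracle for founder contributions -------
# transmits single founder-labelled alleles down the pedigree and
# averages the realised founder-allele proportion over replicates
mcFounderContribution <- function(rec, topo, cohort, founder, nRep = 1000) {
  si <- match(rec$sire[match(topo, rec$id)], topo)
  di <- match(rec$dam[match(topo, rec$id)], topo)
  n <- length(topo)
  lab1 <- lab2 <- matrix(0L, nRep, n)
  isF <- topo == founder
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      lab1[, i] <- if (isF[i]) 1L else 0L
    } else {
      pick <- runif(nRep) < 0.5
      lab1[, i] <- ifelse(pick, lab1[, si[i]], lab2[, si[i]])
    }
    if (is.na(di[i])) {
      lab2[, i] <- if (isF[i]) 1L else 0L
    } else {
      pick <- runif(nRep) < 0.5
      lab2[, i] <- ifelse(pick, lab1[, di[i]], lab2[, di[i]])
    }
  }
  ci <- match(cohort, topo)
  mean((lab1[, ci, drop = FALSE] + lab2[, ci, drop = FALSE]) / 2)
}

# ---- small builders ----------------------------------------------------
# a GenotypeMatrix with given dosage rows on one chromosome
toyGenotypes <- function(calls, bp = NULL, chrom = "1") {
  calls <- as.matrix(calls)
  if (is.null(bp)) bp <- seq_len(nrow(calls)) * 10000
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("ind", seq_len(ncol(calls)))
  GenotypeMatrix(calls,
                 data.frame(chrom = chrom, bp = bp,
                            id = paste0("s", seq_len(nrow(calls))),
                            A1 = "A", A2 = "B"))
}

writePlinkToy <- function(dir, ped, map) {
  pedPath <- file.path(dir, "toy.ped")
  mapPath <- file.path(dir, "toy.map")
  writeLines(ped, pedPath)
  writeLines(map, mapPath)
  list(ped = pedPath, map = mapPath)
}
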