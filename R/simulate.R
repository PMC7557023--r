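#' Configure the synthetic-data generator
#'
#' Returns a validated [SimConfig-class].  The defaults encode the stylised
#' demographic history the analysis modules assume: 22 founders (10 males,
#' 12 females) starting around 1920, a severe bottleneck in 1946 sparing 17
#' dogs, litter sizes averaging 6.5 puppies, parents recruited between 2
#' and 6 years of age (giving a ~4-year generation interval), mean lifespan
#' 8.2 years, and a popular-sire usage skew.  The SNP panel defaults to
#' 5000 markers on ten 60-Mb autosomes with founder allele frequencies
#' drawn from Beta(0.5, 0.5) (a realistic folded frequency spectrum) and a
#' Haldane recombination map at 1 cM/Mb.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param nFounderMales,nFounderFemales founder counts.
#' @param startYear,nYears simulated period (`startYear` ...
#'   `startYear + nYears - 1`).
#' @param bottleneckYear,bottleneckSurvivors bottleneck position and the
#'   number of animals surviving it.
#' @param sireSkew popular-sire skew knob: 0 = uniform sire usage;
#'   larger values concentrate matings on few males (gamma-weighted
#'   Dirichlet with concentration `1/sireSkew`).
#' @param litterMean mean litter size (truncated-Poisson, >= 1).
#' @param littersPerYear litters produced per year (capped by the number
#'   of eligible dams).
#' @param matingMinAge,matingMaxAge parental age window, years.
#' @param lifespanMean,lifespanSd normal lifespan parameters, years.
#' @param nSnps,chromLengthsMb,cmPerMb,freqBeta SNP panel for gene
#'   dropping: marker count, autosome lengths (Mb), map density, and the
#'   Beta shape pair for founder allele frequencies.
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(seed = 1L, nFounderMales = 10, nFounderFemales = 12,
                      startYear = 1920, nYears = 40, bottleneckYear = 1946,
                      bottleneckSurvivors = 17, sireSkew = 2,
                      litterMean = 6.5, littersPerYear = 8,
                      matingMinAge = 2, matingMaxAge = 6,
                      lifespanMean = 8.2, lifespanSd = 2.2,
                      nSnps = 5000, chromLengthsMb = rep(60, 10),
                      cmPerMb = 1, freqBeta = c(0.5, 0.5)) {
  new("SimConfig", seed = as.integer(seed),
      nFounderMales = as.integer(nFounderMales),
      nFounderFemales = as.integer(nFounderFemales),
      startYear = as.integer(startYear), nYears = as.integer(nYears),
      bottleneckYear = as.integer(bottleneckYear),
      bottleneckSurvivors = as.integer(bottleneckSurvivors),
      sireSkew = sireSkew, litterMean = litterMean,
      littersPerYear = as.integer(littersPerYear),
      matingMinAge = as.integer(matingMinAge),
      matingMaxAge = as.integer(matingMaxAge),
      lifespanMean = lifespanMean, lifespanSd = lifespanSd,
      nSnps = as.integer(nSnps), chromLengthsMb = chromLengthsMb,
      cmPerMb = cmPerMb, freqBeta = freqBeta)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: seed", object@seed, "|",
      object@nFounderMales + object@nFounderFemales, "founders,",
      object@startYear, "-", object@startYear + object@nYears - 1,
      "| bottleneck", object@bottleneckYear, "->",
      object@bottleneckSurvivors, "survivors | sire skew",
      object@sireSkew, "\n")
})

truncPois <- function(n, lambda) {
  x <- rpois(n, lambda)
  while (any(x == 0)) x[x == 0] <- rpois(sum(x == 0), lambda)
  x
}

#' Simulate a bottlenecked pedigree with popular-sire skew
#'
#' Founders are unrelated; each year, litters pair a dam drawn uniformly
#' (without replacement within the year) with a sire drawn from a skewed
#' usage distribution, litter sizes are truncated Poisson, and all but a
#' configured handful of animals are removed in the bottleneck year.
#' Dates, sexes and lifespans are consistent, and the output is
#' deterministic under the configured seed.
#'
#' @param cfg a [SimConfig-class] from [simConfig()].
#' @return list with `pedigree` (a validated [Pedigree-class]) and `truth`
#'   (founder ids, bottleneck survivors, and the generating config).
#' @export
simulatePedigree <- function(cfg) {
  withSeed(cfg@seed, {
    nF <- cfg@nFounderMales + cfg@nFounderFemales
    id <- sprintf("F%03d", seq_len(nF))
    sex <- rep(c("male", "female"), c(cfg@nFounderMales, cfg@nFounderFemales))
    birthYear <- cfg@startYear -
      sample(seq(cfg@matingMinAge, cfg@matingMaxAge), nF, replace = TRUE)
    birth <- as.Date(paste0(birthYear, "-01-01")) +
      sample(0:364, nF, replace = TRUE)
    life <- pmax(0.5, rnorm(nF, cfg@lifespanMean, cfg@lifespanSd))
    rec <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                      sex = sex, birth_date = birth,
                      death_date = birth + round(life * 365.25),
                      stringsAsFactors = FALSE)
    counter <- 0L
    survivorIds <- character(0)
    for (y in seq(cfg@startYear, cfg@startYear + cfg@nYears - 1L)) {
      refDate <- as.Date(paste0(y, "-01-01"))
      age <- as.numeric(refDate - rec$birth_date) / 365.25
      alive <- rec$death_date > refDate
      canBreed <- alive & age >= cfg@matingMinAge & age <= cfg@matingMaxAge
      sires <- rec$id[canBreed & rec$sex == "male"]
      dams <- rec$id[canBreed & rec$sex == "female"]
      if (!length(sires) || !length(dams))
        stop("population extinct in year ", y,
             ": no eligible breeding pair; adjust simulation parameters")
      nLit <- min(cfg@littersPerYear, length(dams))
      litDams <- sample(dams, nLit)
      w <- if (cfg@sireSkew <= 0) rep(1, length(sires))
           else rgamma(length(sires), shape = 1 / cfg@sireSkew, rate = 1)
      litSires <- sample(sires, nLit, replace = TRUE,
                         prob = w / sum(w))
      sizes <- truncPois(nLit, cfg@litterMean)
      litDates <- refDate + sample(0:364, nLit, replace = TRUE)
      for (l in seq_len(nLit)) {
        ids <- sprintf("D%06d", counter + seq_len(sizes[l]))
        counter <- counter + sizes[l]
        life <- pmax(0.5, rnorm(sizes[l], cfg@lifespanMean, cfg@lifespanSd))
        rec <- rbind(rec, data.frame(
          id = ids, sire = litSires[l], dam = litDams[l],
          sex = sample(c("male", "female"), sizes[l], replace = TRUE),
          birth_date = litDates[l],
          death_date = litDates[l] + round(life * 365.25),
          stringsAsFactors = FALSE))
      }
      if (y == cfg@bottleneckYear) {
        eoy <- as.Date(paste0(y, "-12-31"))
        age <- as.numeric(eoy - rec$birth_date) / 365.25
        aliveIdx <- which(rec$death_date > eoy & age <= cfg@matingMaxAge)
        if (length(aliveIdx) > cfg@bottleneckSurvivors) {
          # keep both sexes represented among the survivors
          males <- aliveIdx[rec$sex[aliveIdx] == "male"]
          females <- aliveIdx[rec$sex[aliveIdx] == "female"]
          nm <- min(length(males), max(2L, cfg@bottleneckSurvivors %/% 2L))
          nf <- min(length(females), cfg@bottleneckSurvivors - nm)
          survivors <- c(sample(males, nm), sample(females, nf))
          rest <- setdiff(aliveIdx, survivors)
          extra <- cfg@bottleneckSurvivors - length(survivors)
          if (extra > 0 && length(rest))
            survivors <- c(survivors, sample(rest, min(extra, length(rest))))
          cull <- c(setdiff(aliveIdx, survivors),
                    which(rec$death_date > eoy & age > cfg@matingMaxAge))
          rec$death_date[cull] <- eoy
        } else survivors <- aliveIdx
        survivorIds <- rec$id[survivors]
      }
    }
    ped <- Pedigree(rec)
    list(pedigree = ped,
         truth = list(founders = id,
                      bottleneck_survivors =
                        if (exists("survivorIds")) survivorIds
                        else character(0),
                      config = cfg))
  })
}

# one gamete from parent haplotypes under a Haldane map
gameteFrom <- function(h1, h2, o1, o2, chromIdx, chromStartBp, chromLenBp,
                       cmPerMb) {
  hap <- integer(length(h1))
  orig <- integer(length(h1))
  for (c in seq_along(chromIdx)) {
    idx <- chromIdx[[c]]
    morgans <- chromLenBp[c] / 1e6 * cmPerMb / 100
    k <- rpois(1, morgans)
    cur <- sample(1:2, 1)
    if (k == 0) {
      src <- rep(cur, length(idx))
    } else {
      bks <- sort(runif(k, 0, chromLenBp[c]))
      seg <- findInterval(chromStartBp[[c]], bks)
      src <- ifelse((seg + cur) %% 2 == 0, 2L, 1L)
    }
    pick1 <- src == 1L
    hap[idx] <- ifelse(pick1, h1[idx], h2[idx])
    orig[idx] <- ifelse(pick1, o1[idx], o2[idx])
  }
  list(hap = hap, orig = orig)
}

#' Drop founder alleles through a pedigree
#'
#' Gene dropping: founder haplotypes are drawn from the configured allele
#' frequency spectrum; each offspring receives one recombinant gamete per
#' parent under a Haldane (no-interference) crossover model at the
#' configured map density.  An animal with an unknown parent receives a
#' fresh founder-like haplotype on that side.  Genotypes are returned on
#' the SNP panel; founder-haplotype origin labels are tracked so the true
#' autozygous genome fraction of every animal (the realised analogue of
#' the pedigree inbreeding coefficient) is available in
#' `metadata(x)$autozygosity`.
#'
#' @param ped a [Pedigree-class].
#' @param cfg a [SimConfig-class]; the panel fields and `seed` are used.
#' @return A [GenotypeMatrix-class]; `metadata()` carries `autozygosity`
#'   (named per-animal fraction) and `founder_freqs`.
#' @export
geneDrop <- function(ped, cfg) {
  withSeed(cfg@seed + 1000L, {
    rec <- ped@records
    ids <- ped@topo
    nA <- length(ids)
    lenBp <- cfg@chromLengthsMb * 1e6
    nPer <- diff(round(c(0, cumsum(lenBp)) / sum(lenBp) * cfg@nSnps))
    chroms <- rep(seq_along(lenBp), nPer)
    bp <- unlist(lapply(seq_along(lenBp), function(c) {
      sort(sample.int(lenBp[c], nPer[c]))
    }))
    m <- length(bp)
    p <- pmin(pmax(rbeta(m, cfg@freqBeta[1], cfg@freqBeta[2]), 1e-4),
              1 - 1e-4)
    chromIdx <- split(seq_len(m), chroms)
    chromStartBp <- split(bp, chroms)
    H1 <- H2 <- matrix(0L, m, nA, dimnames = list(NULL, ids))
    O1 <- O2 <- matrix(0L, m, nA, dimnames = list(NULL, ids))
    nextOrig <- 0L
    freshHap <- function() rbinom(m, 1L, p)
    si <- match(rec$sire[match(ids, rec$id)], ids)
    di <- match(rec$dam[match(ids, rec$id)], ids)
    for (i in seq_len(nA)) {
      for (side in 1:2) {
        pIdx <- if (side == 1) si[i] else di[i]
        if (is.na(pIdx)) {
          hap <- freshHap()
          nextOrig <- nextOrig + 1L
          orig <- rep(nextOrig, m)
        } else {
          gm <- gameteFrom(H1[, pIdx], H2[, pIdx], O1[, pIdx], O2[, pIdx],
                           chromIdx, chromStartBp, lenBp, cfg@cmPerMb)
          hap <- gm$hap
          orig <- gm$orig
        }
        if (side == 1) { H1[, i] <- hap; O1[, i] <- orig }
        else { H2[, i] <- hap; O2[, i] <- orig }
      }
    }
    calls <- H1 + H2
    map <- data.frame(chrom = as.character(chroms), bp = bp,
                      id = sprintf("snp%05d", seq_len(m)),
                      A1 = "A", A2 = "B")
    out <- GenotypeMatrix(calls, map, individuals = ids)
    metadata(out)$autozygosity <- setNames(colMeans(O1 == O2), ids)
    metadata(out)$founder_freqs <- p
    out
  })
}

# dosage vector with a given alt-allele count distributed over 2n slots
genoFromAltCount <- function(n, altCount, allCarriers = FALSE) {
  g <- integer(n)
  if (allCarriers) {
    stopifnot(altCount >= n, altCount <= 2 * n)
    g <- rep(1L, n)
    extra <- altCount - n
    if (extra > 0) g[sample.int(n, extra)] <- 2L
  } else if (altCount > 0) {
    stopifnot(altCount <= 2 * n)
    slot <- rep(seq_len(n), 2)
    g <- tabulate(slot[sample.int(2 * n, altCount)], nbins = n)
  }
  as.integer(g)
}

#' Simulate a joint cohort/control variant table with planted categories
#'
#' Emits an aggregated variant table (cohort of `cohortN` sequenced
#' individuals against `controlN` controls) with planted variants that
#' satisfy the filter definitions by construction: `private` variants
#' carried by every cohort sample and absent from controls, `rare`
#' variants carried by some cohort samples and absent from controls, and
#' `enriched` variants whose control frequency lies inside
#' `enrichedControlRange` with a cohort frequency strictly above twice the
#' control value.  Background variants are common in the controls and fail
#' every filter.
#'
#' @param nVariants total number of variants.
#' @param planted named integer vector with any of `private`, `rare`,
#'   `enriched`; must sum to at most `nVariants`.
#' @param seed integer seed.
#' @param cohortN,controlN diploid panel sizes (defaults 39 and 614).
#' @param enrichedControlRange open interval for planted control
#'   frequencies; must lie strictly inside (0, 0.10) or the request is
#'   infeasible.
#' @return list with `table` (see [makeVariantTable()]; extra column `id`)
#'   and `truth` (data.frame `id`, `category`).
#' @export
simulateVariantTable <- function(nVariants, planted = c(private = 5,
                                                        rare = 10,
                                                        enriched = 5),
                                 seed = 1L, cohortN = 39, controlN = 614,
                                 enrichedControlRange = c(0.01, 0.09)) {
  planted <- planted[planted > 0]
  bad <- setdiff(names(planted), c("private", "rare", "enriched"))
  if (length(bad)) stop("unknown planted categor(ies): ",
                        paste(bad, collapse = ", "))
  if (sum(planted) > nVariants)
    stop("planted counts exceed nVariants")
  if (enrichedControlRange[1] <= 0 || enrichedControlRange[2] >= 0.10)
    stop("infeasible enrichment request: control frequencies must lie ",
         "strictly inside (0, 0.10)")
  withSeed(seed, {
    cats <- sample(rep(c(names(planted), "background"),
                       c(planted, nVariants - sum(planted))))
    cohortG <- matrix(0L, nVariants, cohortN)
    controlG <- matrix(0L, nVariants, controlN)
    for (v in seq_len(nVariants)) {
      switch(cats[v],
        private = {
          extra <- rbinom(1, cohortN, 0.2)
          cohortG[v, ] <- genoFromAltCount(cohortN, cohortN + extra,
                                           allCarriers = TRUE)
        },
        rare = {
          nc <- sample.int(min(10L, cohortN - 1L), 1)
          cohortG[v, sample.int(cohortN, nc)] <- 1L
        },
        enriched = {
          fc <- runif(1, enrichedControlRange[1], enrichedControlRange[2])
          ctrlAlt <- max(1L, round(fc * 2 * controlN))
          fcReal <- ctrlAlt / (2 * controlN)
          cohortAlt <- min(2L * cohortN,
                           as.integer(ceiling(2 * fcReal * 2 * cohortN)) + 1L)
          controlG[v, ] <- genoFromAltCount(controlN, ctrlAlt)
          cohortG[v, ] <- genoFromAltCount(cohortN, cohortAlt)
        },
        background = {
          u <- runif(1, 0.15, 0.6)
          controlG[v, ] <- genoFromAltCount(controlN,
                                            round(u * 2 * controlN))
          cohortG[v, ] <- genoFromAltCount(cohortN,
                                           round(runif(1, 0, 0.6) * 2 *
                                                 cohortN))
        })
    }
    cons <- sample(consequenceLevels, nVariants, replace = TRUE,
                   prob = c(0.08, 0.12, 0.02, 0.01, 0.01, 0.01, 0.7, 0.05))
    gene <- sprintf("GENE%03d", sample.int(60, nVariants, replace = TRUE))
    gene[cons == "non-coding" & runif(nVariants) < 0.5] <- NA_character_
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nVariants, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "x")
    info <- data.frame(id = sprintf("var%05d", seq_len(nVariants)),
                       chrom = as.character(sample.int(38, nVariants,
                                                       replace = TRUE)),
                       pos = sample.int(6e7, nVariants),
                       ref = ref, alt = alt, gene = gene,
                       consequence = cons, stringsAsFactors = FALSE)
    tbl <- makeVariantTable(info, cohortG, controlG)
    list(table = tbl,
         truth = data.frame(id = info$id, category = cats,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate owner-reported health-survey records
#'
#' Independent Bernoulli draws per dog and condition; dogs without any
#' condition are kept as rows with missing category/label so that survey
#' denominators are preserved.
#'
#' @param conditions data.frame with `category`, `label`, `prevalence`.
#' @param nDogs number of surveyed dogs.
#' @param seed integer seed.
#' @return data.frame with `dog_id`, `category`, `label` (one row per
#'   dog-condition, plus one all-`NA` row per healthy dog).
#' @export
simulateSurvey <- function(conditions, nDogs, seed = 1L) {
  if (any(conditions$prevalence < 0 | conditions$prevalence > 1))
    stop("prevalences must lie in [0, 1]")
  withSeed(seed, {
    dogs <- sprintf("dog%05d", seq_len(nDogs))
    rows <- lapply(seq_len(nrow(conditions)), function(k) {
      hit <- runif(nDogs) < conditions$prevalence[k]
      if (!any(hit)) return(NULL)
      data.frame(dog_id = dogs[hit], category = conditions$category[k],
                 label = conditions$label[k], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    affected <- if (is.null(out)) character(0) else unique(out$dog_id)
    healthy <- setdiff(dogs, affected)
    if (length(healthy))
      out <- rbind(out, data.frame(dog_id = healthy, category = NA_character_,
                                   label = NA_character_,
                                   stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out
  })
}
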