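#' Identify the contributing founders of a population
#'
#' A founder is an animal with both parents unknown.  Only founders with at
#' least one descendant in the most recent birth cohort (or in an explicit
#' `cohort`) are returned, i.e. founders whose genetic material can still be
#' present in the current population.
#'
#' @param ped a [Pedigree-class] object.
#' @param cohort optional character vector of ids defining the cohort of
#'   interest; defaults to all animals born in the latest known birth year.
#' @return character vector of founder ids.
#' @export
findFounders <- function(ped, cohort = NULL) {
  rec <- ped@records
  founders <- rec$id[is.na(rec$sire) & is.na(rec$dam)]
  if (is.null(cohort)) cohort <- latestCohort(ped)
  if (!length(cohort)) return(character(0))
  anc <- ancestorClosure(ped, cohort)
  founders[founders %in% anc]
}

latestCohort <- function(ped) {
  rec <- ped@records
  yr <- as.integer(format(rec$birth_date, "%Y"))
  if (all(is.na(yr))) return(rec$id)
  rec$id[!is.na(yr) & yr == max(yr, na.rm = TRUE)]
}

#' Expected genetic contribution of founders to a cohort
#'
#' The contribution of a founder to an animal is 1 for the founder itself
#' and otherwise the mean of the parental contributions, with an unknown
#' parent contributing 0.  The cohort value is the mean over cohort
#' members.  Over all founders the contributions sum to the cohort-mean
#' known-ancestry fraction (exactly 1 when the pedigree is fully known).
#'
#' @param ped a [Pedigree-class] object.
#' @param cohort character vector of cohort ids; defaults to the most
#'   recent birth cohort.
#' @param founders founder ids to evaluate; defaults to every animal with
#'   both parents unknown.
#' @return named numeric vector of expected contribution fractions.
#' @export
founderContribution <- function(ped, cohort = NULL, founders = NULL) {
  rec <- ped@records
  if (is.null(cohort)) cohort <- latestCohort(ped)
  missing <- setdiff(cohort, rec$id)
  if (length(missing))
    stop("cohort id(s) not in pedigree: ", paste(missing, collapse = ", "))
  if (is.null(founders))
    founders <- rec$id[is.na(rec$sire) & is.na(rec$dam)]
  ids <- ped@topo
  si <- match(rec$sire[match(ids, rec$id)], ids)
  di <- match(rec$dam[match(ids, rec$id)], ids)
  ci <- match(cohort, ids)
  out <- setNames(numeric(length(founders)), founders)
  for (f in founders) {
    contrib <- numeric(length(ids))
    contrib[match(f, ids)] <- 1
    start <- match(f, ids)
    for (i in seq(from = start, to = length(ids))) {
      if (ids[i] == f) next
      cs <- if (!is.na(si[i])) contrib[si[i]] else 0
      cd <- if (!is.na(di[i])) contrib[di[i]] else 0
      contrib[i] <- 0.5 * (cs + cd)
    }
    out[f] <- mean(contrib[ci])
  }
  out
}

#' Pedigree completeness index
#'
#' Fraction of known ancestor slots within `generations` generations:
#' each known parent fills one slot and opens its own parental slots one
#' generation deeper; the denominator is \eqn{2 + 4 + \dots + 2^g}.  An
#' ancestor appearing several times in the pedigree counts once per slot.
#'
#' @param ped a [Pedigree-class] object.
#' @param generations depth of the ancestor pedigree considered (>= 1).
#' @return named numeric vector of completeness indices in `[0, 1]`.
#' @export
pedigreeCompleteness <- function(ped, generations = 5) {
  if (generations < 1) stop("generations must be >= 1")
  rec <- ped@records
  ids <- ped@topo
  si <- match(rec$sire[match(ids, rec$id)], ids)
  di <- match(rec$dam[match(ids, rec$id)], ids)
  n <- length(ids)
  # known[, g] = number of known ancestors of i in generations 1..g
  counts <- matrix(0, n, generations)
  for (g in seq_len(generations)) {
    for (i in seq_len(n)) {
      k <- 0
      for (p in c(si[i], di[i])) {
        if (!is.na(p)) k <- k + 1 + if (g > 1) counts[p, g - 1] else 0
      }
      counts[i, g] <- k
    }
  }
  denom <- sum(2^seq_len(generations))
  setNames(counts[, generations] / denom, ids)[rec$id]
}

#' @rdname popularSireStats
#' @param litterMean observed mean litter size.
#' @export
popularSireThreshold <- function(litterMean) {
  if (litterMean <= 0) stop("litterMean must be positive")
  as.integer(ceiling(5 * litterMean))
}

#' Popular-sire statistics
#'
#' A popular sire is a male whose offspring count reaches `threshold`,
#' by default the number of puppies in five litters of the observed mean
#' litter size (rounded up) -- with a mean litter of 6.5 this gives 33.
#' Reports how concentrated breeding is: the share of sires that are
#' popular and the share of all offspring those sires produced.
#'
#' @param ped a [Pedigree-class] object.
#' @param threshold minimum offspring count for a popular sire; `NULL`
#'   derives it from the pedigree's mean litter size.
#' @param topN how many top sires to list.
#' @return list with `threshold`, `n_sires`, `n_popular`,
#'   `sire_share_popular`, `offspring_share_of_popular` and `top_sires`
#'   (data.frame id/offspring, decreasing).
#' @export
popularSireStats <- function(ped, threshold = NULL, topN = 10) {
  rec <- ped@records
  isSire <- rec$id %in% rec$sire
  if (!any(isSire)) stop("pedigree contains no sires")
  if (is.null(threshold))
    threshold <- popularSireThreshold(litterIntervalStats(ped)$mean_litter_size)
  sires <- rec[isSire, c("id", "offspring_count")]
  sires <- sires[order(-sires$offspring_count, sires$id), ]
  popular <- sires$offspring_count >= threshold
  totalOff <- sum(sires$offspring_count)
  list(threshold = as.integer(threshold),
       n_sires = nrow(sires),
       n_popular = sum(popular),
       sire_share_popular = sum(popular) / nrow(sires),
       offspring_share_of_popular =
         if (totalOff > 0) sum(sires$offspring_count[popular]) / totalOff
         else 0,
       top_sires = utils::head(sires, topN))
}

#' Litter-size and generation-interval statistics
#'
#' A litter is the set of offspring sharing sire, dam and birth date.  The
#' generation interval is the mean age of parents at the birth of their
#' offspring, in years, averaged over all dated parent-offspring pairs.
#'
#' @param ped a [Pedigree-class] object.
#' @return list with `mean_litter_size`, `n_litters`,
#'   `mean_generation_interval` (years; `NA` when no dated pairs) and
#'   `n_parent_offspring_pairs`.
#' @export
litterIntervalStats <- function(ped) {
  rec <- ped@records
  dated <- !is.na(rec$sire) & !is.na(rec$dam) & !is.na(rec$birth_date)
  if (!any(dated)) stop("no litters with known sire, dam and birth date")
  key <- paste(rec$sire[dated], rec$dam[dated], rec$birth_date[dated])
  sizes <- as.integer(table(key))
  bp <- rec$birth_date[match(rec$sire, rec$id)]
  ageS <- as.numeric(rec$birth_date - bp) / 365.25
  bp <- rec$birth_date[match(rec$dam, rec$id)]
  ageD <- as.numeric(rec$birth_date - bp) / 365.25
  ages <- c(ageS[!is.na(ageS)], ageD[!is.na(ageD)])
  list(mean_litter_size = mean(sizes),
       n_litters = length(sizes),
       mean_generation_interval = if (length(ages)) mean(ages) else NA_real_,
       n_parent_offspring_pairs = length(ages))
}

#' Longevity by birth-year cohort
#'
#' Age at death in fractional years, summarised per birth year.  Years with
#' `min_records` or fewer dated animals are excluded (strictly more than
#' `min_records` records are required), so that sparsely recorded or still
#' partly alive cohorts do not distort the trend.
#'
#' @param ped a [Pedigree-class] object.
#' @param min_records minimum (exclusive) number of dated records per
#'   retained birth year.
#' @return list with `per_year` (data.frame: year, n, mean, median),
#'   `overall` (n, mean, median over retained years) and `by_sex` mean ages.
#' @export
longevityStats <- function(ped, min_records = 100) {
  rec <- ped@records
  ok <- !is.na(rec$birth_date) & !is.na(rec$death_date)
  rec <- rec[ok, ]
  age <- as.numeric(rec$death_date - rec$birth_date) / 365.25
  year <- as.integer(format(rec$birth_date, "%Y"))
  tab <- do.call(rbind, lapply(split(seq_along(age), year), function(i) {
    data.frame(year = year[i[1]], n = length(i),
               mean = mean(age[i]), median = median(age[i]))
  }))
  if (is.null(tab))
    tab <- data.frame(year = integer(), n = integer(),
                      mean = numeric(), median = numeric())
  keep <- tab$n > min_records
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL
  inYears <- year %in% tab$year
  bySex <- tapply(age[inYears], rec$sex[inYears], mean)
  list(per_year = tab,
       overall = list(n = sum(inYears),
                      mean = if (any(inYears)) mean(age[inYears]) else NA_real_,
                      median = if (any(inYears)) median(age[inYears])
                               else NA_real_),
       by_sex = bySex)
}

#' Read health-survey records
#'
#' Tab-separated file with columns `dog_id`, `condition_category`,
#' `condition_label`, one row per reported condition; dogs without any
#' condition appear with empty category/label so the denominator is
#' preserved.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `dog_id`, `category`, `label`.
#' @export
readSurvey <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                  na.strings = c("", "NA"), comment.char = "#")
  names(x) <- sub("^condition_", "", names(x))
  x[c("dog_id", "category", "label")]
}

#' Summarise an owner-reported health survey
#'
#' Counts dogs with at least one reported condition and per-category /
#' per-disorder tallies.  A dog with several disorders is counted once in
#' the "any condition" total but once per category it appears in, so
#' per-category counts may sum to more than the number of affected dogs.
#' Percentages are computed against the number of surveyed dogs and
#' rounded to one decimal only for presentation.
#'
#' @param records data.frame with columns `dog_id`, `category`, `label`
#'   (one row per condition; `NA` category for healthy dogs).
#' @param vocabulary optional character vector of allowed category labels;
#'   unknown categories raise an error.
#' @return list with `n_dogs`, `n_with_any_condition`, `pct_any_condition`,
#'   and data.frames `by_category` and `by_label` (n, pct).
#' @export
surveySummary <- function(records, vocabulary = NULL) {
  if (!nrow(records)) stop("empty survey")
  nDogs <- length(unique(records$dog_id))
  hasCond <- !is.na(records$category)
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(records$category[hasCond]), vocabulary)
    if (length(bad))
      stop("unknown condition categor(ies): ", paste(bad, collapse = ", "))
  }
  nAny <- length(unique(records$dog_id[hasCond]))
  pct <- function(k) round(100 * k / nDogs, 1)
  tallyBy <- function(col) {
    x <- records[hasCond, ]
    cnt <- tapply(x$dog_id, x[[col]], function(d) length(unique(d)))
    if (is.null(cnt) || !length(cnt))
      return(data.frame(name = character(), n = integer(), pct = numeric()))
    df <- data.frame(name = names(cnt), n = as.integer(cnt),
                     pct = pct(as.integer(cnt)))
    df[order(-df$n, df$name), , drop = FALSE]
  }
  list(n_dogs = nDogs,
       n_with_any_condition = nAny,
       pct_any_condition = pct(nAny),
       by_category = tallyBy("category"),
       by_label = tallyBy("label"))
}
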