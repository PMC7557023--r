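trioRecords <- data.frame(id = c("A", "B", "C"),
                          sire = c(NA, NA, "A"),
                          dam = c(NA, NA, "B"))

test_that("pedigree construction validates structure and fills gaps", {
  ped <- Pedigree(trioRecords)
  expect_s4_class(ped, "Pedigree")
  expect_equal(length(ped), 3L)
  topo <- pedigreeIds(ped)
  expect_true(match("A", topo) < match("C", topo))
  expect_true(match("B", topo) < match("C", topo))

  # referenced-but-absent parent materialised as a founder
  ped2 <- Pedigree(data.frame(id = "C", sire = "A", dam = "D"))
  expect_equal(length(ped2), 3L)
  recD <- pedigreeRecords(ped2)["D", ]
  expect_true(is.na(recD$sire) && is.na(recD$dam))
  expect_identical(recD$sex, "female")

  expect_error(Pedigree(data.frame(id = "A", sire = "A", dam = NA)),
               "cycle")
  expect_error(Pedigree(data.frame(id = c("A", "A"), sire = NA, dam = NA)),
               "duplicate")
  # X used as sire of one animal and dam of another
  expect_error(Pedigree(data.frame(id = c("X", "B", "C"),
                                   sire = c(NA, "X", NA),
                                   dam = c(NA, NA, "X"))),
               "sex|both sire and dam")
  # longer cycle through two generations
  expect_error(Pedigree(data.frame(id = c("A", "B"),
                                   sire = c("B", "A"),
                                   dam = c(NA, NA))),
               "cycle|sex")
})

test_that("pedigree CSV reader applies column remapping and unknown codes", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("animal,father,mother,sex,born",
               "A,0,0,M,1990",
               "B,0,0,F,1991-05-20",
               "C,A,B,M,1995-05-20"), f)
  ped <- readPedigree(f, columns = c(id = "animal", sire = "father",
                                     dam = "mother", sex = "sex",
                                     birth_date = "born"))
  rec <- pedigreeRecords(ped)
  expect_equal(length(ped), 3L)
  expect_true(is.na(rec["A", "sire"]))
  expect_identical(rec["C", "sire"], "A")
  # year-only dates parse to July 1
  expect_equal(rec["A", "birth_date"], as.Date("1990-07-01"))
})

test_that("tabular kinship reproduces textbook coancestries", {
  # parent-offspring with unknown other parent
  K <- kinshipValues(kinshipTabular(Pedigree(
    data.frame(id = c("A", "C"), sire = c(NA, "A"), dam = c(NA, NA)))))
  expect_equal(K["A", "C"], 0.25)

  # full sibs and their inbred offspring
  ped <- Pedigree(data.frame(id = c("A", "B", "X", "Y", "Z"),
                             sire = c(NA, NA, "A", "A", "X"),
                             dam = c(NA, NA, "B", "B", "Y")))
  K <- kinshipValues(kinshipTabular(ped))
  expect_equal(K["X", "Y"], 0.25)
  expect_equal(K["Z", "Z"], 0.625)
  expect_equal(unname(inbreedingFped(ped)["Z"]), 0.25)
})

test_that("tabular kinship equals the path-counting oracle", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      rec <- randomPedigree(n = 25, nFounders = 6)
      ped <- Pedigree(rec)
      K <- kinshipValues(kinshipTabular(ped))
      ids <- pedigreeIds(ped)
      Ko <- oracleKinshipMatrix(pedigreeRecords(ped), ids)
      expect_lt(max(abs(K[ids, ids] - Ko)), 1e-12)
    }
  })
})

test_that("kinship matrices are symmetric PSD with the diagonal identity", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      ped <- Pedigree(randomPedigree(n = 40, nFounders = 8))
      K <- kinshipValues(kinshipTabular(ped))
      expect_equal(K, t(K))
      expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
                -1e-10)
      F <- inbreedingFped(ped)
      expect_equal(unname(2 * diag(K)[names(F)] - 1), unname(F),
                   tolerance = 1e-12)
      rec <- pedigreeRecords(ped)
      unknown <- is.na(rec$sire) | is.na(rec$dam)
      expect_true(all(F[rec$id[unknown]] == 0))
    }
  })
})

test_that("repeated full-sib mating follows the classical F recurrence", {
  # line: F_t = 0.25 (1 + 2 F_{t-1} + F_{t-2})
  rec <- data.frame(id = c("M0", "F0"), sire = NA, dam = NA)
  for (t in 1:6) {
    rec <- rbind(rec, data.frame(
      id = c(paste0("M", t), paste0("F", t)),
      sire = paste0("M", t - 1), dam = paste0("F", t - 1)))
  }
  F <- inbreedingFped(Pedigree(rec))
  # generation 1 stems from unrelated founders (F = 0); sib mating starts
  # compounding from generation 2 onwards
  got <- vapply(1:6, function(t) unname(F[paste0("M", t)]), numeric(1))
  recur <- numeric(5)
  fm1 <- 0; fm2 <- 0
  for (t in 1:5) {
    recur[t] <- 0.25 * (1 + 2 * fm1 + fm2)
    fm2 <- fm1; fm1 <- recur[t]
  }
  expect_equal(got, c(0, recur), tolerance = 1e-12)
  expect_equal(got[2:3], c(0.25, 0.375))
  expect_true(all(diff(got) > 0))
})

test_that("mean kinship averages coancestry over the reference set", {
  # four mutually unrelated, non-inbred animals
  ped <- Pedigree(data.frame(id = c("A", "B", "C", "D"), sire = NA, dam = NA))
  mk <- meanKinship(kinshipTabular(ped))
  expect_equal(unname(mk), rep(0.125, 4))
  # single-animal reference
  mk1 <- meanKinship(kinshipTabular(ped), reference = "A")
  expect_equal(unname(mk1["A"]), 0.5)
  # clones of one non-inbred animal: all pairwise f = 0.5
  Kc <- new("KinshipMatrix",
            f = matrix(0.5, 3, 3, dimnames = list(letters[1:3],
                                                  letters[1:3])))
  expect_equal(unname(meanKinship(Kc)), rep(0.5, 3))
  expect_error(meanKinship(kinshipTabular(ped), reference = character(0)),
               "empty")
  # agreement with oracle row means on a random pedigree
  withr::with_seed(31, {
    ped <- Pedigree(randomPedigree(25, 6))
    ids <- pedigreeIds(ped)
    Ko <- oracleKinshipMatrix(pedigreeRecords(ped), ids)
    mk <- meanKinship(kinshipTabular(ped))
    expect_equal(unname(mk[ids]), unname(rowMeans(Ko)), tolerance = 1e-12)
  })
})

test_that("MK colour groups use a closed yellow interval", {
  g <- mkColorGroups(c(0.305, 0.31, 0.315, 0.32, 0.325))
  expect_equal(as.character(g),
               c("green", "yellow", "yellow", "yellow", "orange"))
  expect_error(mkColorGroups(c(0.2, 1.5)), "0, 1")
})

test_that("founders require descent into the reference cohort", {
  ped <- Pedigree(trioRecords)
  expect_setequal(findFounders(ped, cohort = "C"), c("A", "B"))
  # childless founder excluded
  ped2 <- Pedigree(rbind(trioRecords,
                         data.frame(id = "Z", sire = NA, dam = NA)))
  expect_setequal(findFounders(ped2, cohort = "C"), c("A", "B"))
})

test_that("founder contributions conserve mass and match gene dropping", {
  ped <- Pedigree(trioRecords)
  fc <- founderContribution(ped, cohort = "C")
  expect_equal(unname(fc[c("A", "B")]), c(0.5, 0.5))

  withr::with_seed(41, {
    rec <- randomPedigree(30, 8, pUnknown = 0)  # fully known pedigree
    ped <- Pedigree(rec)
    cohort <- utils::tail(pedigreeIds(ped), 8)
    fc <- founderContribution(ped, cohort = cohort)
    expect_equal(sum(fc), 1, tolerance = 1e-12)
    # Monte-Carlo transmission oracle for one founder
    f <- names(which.max(fc))
    nRep <- 10000
    est <- mcFounderContribution(pedigreeRecords(ped), pedigreeIds(ped),
                                 cohort, f, nRep = nRep)
    se <- sqrt(fc[[f]] * (1 - fc[[f]]) / nRep)
    expect_lt(abs(est - fc[[f]]), 3 * se + 1e-9)
  })
})

test_that("completeness counts known ancestor slots per generation", {
  # founder: 0; fully known for 5 generations: 1
  rec <- data.frame(id = "X", sire = NA, dam = NA)
  expect_equal(unname(pedigreeCompleteness(Pedigree(rec), 5)), 0)
  # parents known, nothing deeper
  ped <- Pedigree(trioRecords)
  expect_equal(unname(pedigreeCompleteness(ped, 5)["C"]), 2 / 62)
  # complete 5-generation ancestry: chain of full generations
  rec <- data.frame(id = c("m", "f"), sire = NA, dam = NA)
  prevM <- "m"; prevF <- "f"
  for (g in 1:5) {
    rec <- rbind(rec, data.frame(id = c(paste0("m", g), paste0("f", g)),
                                 sire = prevM, dam = prevF))
    prevM <- paste0("m", g); prevF <- paste0("f", g)
  }
  # m5's ancestors: every slot filled by the (duplicated) chain animals
  expect_equal(unname(pedigreeCompleteness(Pedigree(rec), 5)["m5"]), 1)
})

test_that("popular-sire statistics tally offspring concentration", {
  expect_equal(popularSireThreshold(6.5), 33L)
  # 4 sires with 10 offspring each: none popular at threshold 33
  rec <- data.frame(id = sprintf("S%d", 1:4), sire = NA, dam = NA,
                    sex = "male")
  rec <- rbind(rec, data.frame(id = "D1", sire = NA, dam = NA,
                               sex = "female"))
  for (s in sprintf("S%d", 1:4))
    rec <- rbind(rec, data.frame(id = paste0(s, "_", 1:10), sire = s,
                                 dam = "D1", sex = "female"))
  st <- popularSireStats(Pedigree(rec), threshold = 33)
  expect_equal(st$n_sires, 4L)
  expect_equal(st$n_popular, 0L)
  expect_equal(st$offspring_share_of_popular, 0)
  # skewed usage: shares equal a direct tally
  withr::with_seed(51, {
    counts <- rgeom(20, 0.08) + 1
    rec <- data.frame(id = sprintf("S%02d", 1:20), sire = NA, dam = NA,
                      sex = "male")
    rec <- rbind(rec, data.frame(id = "D1", sire = NA, dam = NA,
                                 sex = "female"))
    for (k in 1:20)
      rec <- rbind(rec, data.frame(
        id = sprintf("S%02d_%03d", k, seq_len(counts[k])),
        sire = sprintf("S%02d", k), dam = "D1", sex = "female"))
    st <- popularSireStats(Pedigree(rec), threshold = 15)
    expect_equal(st$n_popular, sum(counts >= 15))
    expect_equal(st$offspring_share_of_popular,
                 sum(counts[counts >= 15]) / sum(counts))
  })
  expect_error(popularSireStats(Pedigree(trioRecords[1:2, ])), "no sires")
})

test_that("litter and generation-interval statistics", {
  rec <- data.frame(id = c("S", "D"), sire = NA, dam = NA,
                    sex = c("male", "female"),
                    birth_date = "2000-07-01")
  rec <- rbind(rec,
               data.frame(id = paste0("a", 1:6), sire = "S", dam = "D",
                          sex = "male", birth_date = "2004-07-01"),
               data.frame(id = paste0("b", 1:7), sire = "S", dam = "D",
                          sex = "male", birth_date = "2005-07-02"))
  st <- litterIntervalStats(Pedigree(rec))
  expect_equal(st$mean_litter_size, 6.5)
  expect_equal(st$n_litters, 2L)
  # parents born 2000, offspring 2004/2005 -> mean parental age 4.5 y
  expect_equal(st$mean_generation_interval,
               mean(rep(c(4, 5), times = c(12, 14))), tolerance = 1e-3)
})

test_that("longevity summaries exclude sparse years strictly", {
  mkRec <- function(year, ages, prefix) {
    data.frame(id = paste0(prefix, seq_along(ages)), sire = NA, dam = NA,
               sex = rep(c("male", "female"), length.out = length(ages)),
               birth_date = sprintf("%d-01-01", year),
               death_date = as.character(
                 as.Date(sprintf("%d-01-01", year)) +
                   round(ages * 365.25)))
  }
  rec <- mkRec(1990, c(8, 9, 10), "a")
  st <- longevityStats(Pedigree(rec), min_records = 0)
  expect_equal(st$per_year$mean, 9, tolerance = 1e-3)
  expect_equal(st$per_year$median, 9, tolerance = 1e-3)
  # exactly min_records records -> excluded (strictly more required)
  rec100 <- mkRec(1991, rep(8, 100), "b")
  st <- longevityStats(Pedigree(rbind(rec, rec100)), min_records = 100)
  expect_false(1991 %in% st$per_year$year)
})

test_that("survey summary recomputes percentages from raw counts", {
  rec <- data.frame(
    dog_id = c(sprintf("d%04d", 1:2726)),
    category = NA_character_, label = NA_character_)
  rec$category[1:586] <- "tumor"
  rec$label[1:586] <- "osteosarcoma"
  rec$category[587:1334] <- "orthopaedic"
  rec$label[587:1334] <- "arthritis"
  s <- surveySummary(rec)
  expect_equal(s$n_dogs, 2726L)
  expect_equal(s$n_with_any_condition, 1334L)
  expect_equal(s$pct_any_condition, 48.9)
  expect_equal(s$by_category$pct[s$by_category$name == "tumor"], 21.5)
  # multi-morbidity: a dog in two categories counted once in the total
  rec2 <- rbind(rec, data.frame(dog_id = "d0001", category = "neurological",
                                label = "polyneuropathy"))
  s2 <- surveySummary(rec2)
  expect_equal(s2$n_with_any_condition, 1334L)
  # empty survey: zero affected
  healthy <- data.frame(dog_id = c("x", "y"), category = NA_character_,
                        label = NA_character_)
  s3 <- surveySummary(healthy)
  expect_equal(s3$n_with_any_condition, 0L)
  expect_equal(s3$pct_any_condition, 0)
  expect_error(surveySummary(rec, vocabulary = "cardiac"), "unknown")
})
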