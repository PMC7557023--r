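#' Build a validated Pedigree from a record table
#'
#' Normalises unknown-parent tokens to `NA`, materialises parents that are
#' referenced but never defined as founder records (their sex inferred from
#' the role they are used in), derives per-animal offspring counts and a
#' topological (parents-before-offspring) order, and runs the structural
#' checks: unique ids, no self-parenting, acyclic parent graph, and no
#' animal used both as a sire and as a dam.
#'
#' @param records data.frame with at least an `id` column; optional columns
#'   `sire`, `dam`, `sex`, `birth_date`, `death_date`, `country`.  Dates may
#'   be `Date`, ISO-8601 strings, or bare years (taken as July 1).
#' @param unknown character tokens (besides `NA`) that mark an unknown
#'   parent; default `""` and `"0"`.
#' @return A [Pedigree-class] object.
#' @examples
#' ped <- Pedigree(data.frame(id = c("A", "B", "C"),
#'                            sire = c(NA, NA, "A"),
#'                            dam  = c(NA, NA, "B")))
#' pedigreeIds(ped)
#' @export
Pedigree <- function(records, unknown = c("", "0")) {
  records <- as.data.frame(records)
  if (!"id" %in% names(records) || !nrow(records))
    stop("records must contain a non-empty 'id' column")
  cleanTok <- function(x) {
    x <- trimws(as.character(x))
    x[!nzchar(x) | x %in% unknown | is.na(x)] <- NA_character_
    x
  }
  id <- cleanTok(records$id)
  if (anyNA(id)) stop("empty animal id")
  if (anyDuplicated(id))
    stop("duplicate id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  n <- length(id)
  getCol <- function(nm) if (nm %in% names(records)) records[[nm]] else
    rep(NA, n)
  sire <- cleanTok(getCol("sire"))
  dam <- cleanTok(getCol("dam"))
  if (any(!is.na(sire) & sire == id) || any(!is.na(dam) & dam == id)) {
    bad <- id[(!is.na(sire) & sire == id) | (!is.na(dam) & dam == id)]
    stop("cycle in parent graph: ", bad[1], " is its own parent")
  }
  sex <- tolower(cleanTok(getCol("sex")))
  sex[sex %in% c("m", "male", "1")] <- "male"
  sex[sex %in% c("f", "female", "2")] <- "female"
  sex[!sex %in% c("male", "female")] <- NA_character_

  birth <- parsePedDate(getCol("birth_date"))
  death <- parsePedDate(getCol("death_date"))
  country <- cleanTok(getCol("country"))

  # materialise referenced-but-absent parents as founders
  refSire <- setdiff(stats::na.omit(sire), id)
  refDam <- setdiff(stats::na.omit(dam), id)
  both <- intersect(refSire, refDam)
  if (length(both))
    stop("animal(s) used as both sire and dam: ",
         paste(both, collapse = ", "))
  extra <- c(refSire, refDam)
  if (length(extra)) {
    id <- c(id, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
    sex <- c(sex, rep(c("male", "female"), c(length(refSire), length(refDam))))
    birth <- c(birth, rep(as.Date(NA), length(extra)))
    death <- c(death, rep(as.Date(NA), length(extra)))
    country <- c(country, rep(NA_character_, length(extra)))
  }

  # sex consistency against parental roles
  sexErr <- c(
    intersect(stats::na.omit(sire), stats::na.omit(dam)),
    id[match(stats::na.omit(sire), id)][sex[match(stats::na.omit(sire), id)]
                                        %in% "female"],
    id[match(stats::na.omit(dam), id)][sex[match(stats::na.omit(dam), id)]
                                       %in% "male"])
  if (length(sexErr))
    stop("sex inconsistency for: ", paste(unique(sexErr), collapse = ", "))
  # animals used as sires are male, as dams female (fill unknowns)
  sex[id %in% sire & is.na(sex)] <- "male"
  sex[id %in% dam & is.na(sex)] <- "female"

  topo <- topoSortPedigree(id, sire, dam)

  bb <- birth[match(sire, id)]
  badDate <- !is.na(birth) & !is.na(bb) & bb >= birth
  bb <- birth[match(dam, id)]
  badDate <- badDate | (!is.na(birth) & !is.na(bb) & bb >= birth)
  if (any(badDate))
    stop("parent born on/after offspring for: ",
         paste(id[badDate], collapse = ", "))

  offspring <- as.integer(table(factor(c(sire, dam), levels = id)))
  rec <- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                    birth_date = birth, death_date = death,
                    country = country, offspring_count = offspring,
                    stringsAsFactors = FALSE)
  rownames(rec) <- rec$id
  new("Pedigree", records = rec, topo = topo)
}

# Kahn topological sort; errors naming a cycle member.
topoSortPedigree <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  si <- match(sire, id)
  di <- match(dam, id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- idx[indeg == 0L]
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    member <- id[setdiff(idx, out)][1]
    stop("cycle detected in parent graph involving: ", member)
  }
  id[out]
}

# ISO-8601 dates; bare years become July 1 of that year.
parsePedDate <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- trimws(as.character(x))
  x[!nzchar(x) | x %in% c("0", "NA")] <- NA_character_
  yearOnly <- !is.na(x) & grepl("^[0-9]{4}$", x)
  x[yearOnly] <- paste0(x[yearOnly], "-07-01")
  as.Date(x, format = "%Y-%m-%d")
}

#' Read a pedigree CSV
#'
#' Reads a comma-separated pedigree file with one row per animal and builds
#' a validated [Pedigree-class].  Column names can be remapped through
#' `columns` for registry exports that use other headers.
#'
#' @param path path to a CSV file with a header row.
#' @param columns named character vector mapping the canonical names
#'   (`id`, `sire`, `dam`, `sex`, `birth_date`, `death_date`, `country`) to
#'   the column names used in the file.
#' @param unknown tokens marking unknown parents/fields (default `""`, `"0"`).
#' @return A [Pedigree-class] object.
#' @export
readPedigree <- function(path,
                         columns = c(id = "id", sire = "sire", dam = "dam",
                                     sex = "sex", birth_date = "birth_date",
                                     death_date = "death_date",
                                     country = "country"),
                         unknown = c("", "0")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, sep = ",", header = TRUE, colClasses = "character",
                    na.strings = character(), check.names = FALSE)
  if (!columns[["id"]] %in% names(raw))
    stop("id column '", columns[["id"]], "' not found in ", path)
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (nm in names(columns)) {
    if (columns[[nm]] %in% names(raw)) out[[nm]] <- raw[[columns[[nm]]]]
  }
  Pedigree(out, unknown = unknown)
}

#' @describeIn Pedigree ids in topological (parents-first) order.
#' @param ped a [Pedigree-class] object.
#' @export
pedigreeIds <- function(ped) ped@topo

#' @describeIn Pedigree the per-animal record table (one row per id).
#' @export
pedigreeRecords <- function(ped) ped@records

#' Number of animals in a pedigree
#' @param x a [Pedigree-class] object.
#' @export
setMethod("length", "Pedigree", function(x) nrow(x@records))

setMethod("show", "Pedigree", function(object) {
  rec <- object@records
  founders <- sum(is.na(rec$sire) & is.na(rec$dam))
  yrs <- range(as.integer(format(rec$birth_date, "%Y")), na.rm = TRUE)
  cat("Pedigree of", nrow(rec), "animals (", founders,
      "with both parents unknown )\n")
  if (all(is.finite(yrs)))
    cat("  birth years:", yrs[1], "-", yrs[2], "\n")
})
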