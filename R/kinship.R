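#' Kinship matrix by the tabular method
#'
#' Computes the matrix of pairwise coancestry (kinship) coefficients
#' \eqn{f_{ij}} by the classical tabular recurrence, processing animals in
#' parents-before-offspring order: founders have \eqn{f_{ii} = 1/2} and zero
#' kinship with earlier non-relatives; an animal \eqn{i} with parents
#' \eqn{s, d} has \eqn{f_{ij} = (f_{sj} + f_{dj})/2} for \eqn{j \ne i} and
#' \eqn{f_{ii} = (1 + f_{sd})/2}.  An unknown parent contributes 0 to the
#' averages, i.e. it is treated as a unique unrelated non-inbred founder.
#'
#' When `subset` is given, only the ancestor closure of the subset is
#' processed and the returned matrix is restricted to the subset ids, so
#' kinship among a recent cohort can be extracted without building the full
#' population matrix.
#'
#' @param ped a [Pedigree-class] object.
#' @param subset optional character vector of ids to restrict the result to.
#' @return A [KinshipMatrix-class]; the diagonal equals \eqn{(1 + F_i)/2}.
#' @examples
#' ped <- Pedigree(data.frame(id = c("A", "B", "X", "Y", "Z"),
#'                            sire = c(NA, NA, "A", "A", "X"),
#'                            dam  = c(NA, NA, "B", "B", "Y")))
#' K <- kinshipTabular(ped)
#' kinshipValues(K)["X", "Y"]   # full sibs: 0.25
#' kinshipValues(K)["Z", "Z"]   # 0.5 * (1 + 0.25)
#' @export
kinshipTabular <- function(ped, subset = NULL) {
  rec <- ped@records
  ids <- ped@topo
  if (!is.null(subset)) {
    missing <- setdiff(subset, rec$id)
    if (length(missing))
      stop("subset id(s) not in pedigree: ", paste(missing, collapse = ", "))
    keep <- ancestorClosure(ped, subset)
    ids <- ids[ids %in% keep]
  }
  n <- length(ids)
  si <- match(rec$sire[match(ids, rec$id)], ids)
  di <- match(rec$dam[match(ids, rec$id)], ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      fs <- if (!is.na(s)) K[s, j] else 0
      fd <- if (!is.na(d)) K[d, j] else 0
      fij <- 0.5 * (fs + fd)
      K[i, j] <- fij
      K[j, i] <- fij
    }
    K[i, i] <- 0.5 * (1 + if (!is.na(s) && !is.na(d)) K[s, d] else 0)
  }
  if (!is.null(subset)) K <- K[subset, subset, drop = FALSE]
  new("KinshipMatrix", f = K)
}

# all ancestors of `ids` (including `ids`)
ancestorClosure <- function(ped, ids) {
  rec <- ped@records
  seen <- character(0)
  frontier <- unique(ids)
  while (length(frontier)) {
    seen <- c(seen, frontier)
    k <- match(frontier, rec$id)
    frontier <- setdiff(stats::na.omit(c(rec$sire[k], rec$dam[k])), seen)
  }
  unique(seen)
}

#' @describeIn kinshipTabular animal ids of a kinship matrix.
#' @param K a [KinshipMatrix-class].
#' @export
kinshipIds <- function(K) rownames(K@f)

#' @describeIn kinshipTabular the numeric coancestry matrix.
#' @export
kinshipValues <- function(K) K@f

setMethod("show", "KinshipMatrix", function(object) {
  f <- object@f
  cat("KinshipMatrix over", nrow(f), "animals; mean f =",
      signif(mean(f[upper.tri(f)]), 4), "\n")
})

#' Pedigree inbreeding coefficients (F_PED)
#'
#' \eqn{F_i} is the kinship of the animal's parents; it is exactly 0
#' whenever either parent is unknown.  Computed from the tabular kinship
#' matrix over the whole pedigree.
#'
#' @param ped a [Pedigree-class] object.
#' @return Named numeric vector of inbreeding coefficients in `[0, 1]`,
#'   one per animal, in pedigree record order.
#' @export
inbreedingFped <- function(ped) {
  rec <- ped@records
  K <- kinshipValues(kinshipTabular(ped))
  si <- match(rec$sire, rownames(K))
  di <- match(rec$dam, rownames(K))
  F <- numeric(nrow(rec))
  known <- !is.na(si) & !is.na(di)
  F[known] <- K[cbind(si[known], di[known])]
  names(F) <- rec$id
  F
}

#' Mean kinship of animals against a reference population
#'
#' The mean kinship of animal \eqn{i} is its average coancestry with every
#' member of a reference set (typically the animals currently available for
#' breeding): \eqn{MK_i = |R|^{-1} \sum_{j \in R} f_{ij}}.  Animals with low
#' MK are the genetically most valuable breeders.  By convention the self
#' term \eqn{f_{ii}} is included when \eqn{i \in R} (`includeSelf = TRUE`);
#' set `includeSelf = FALSE` to average only over the other members.
#'
#' @param K a [KinshipMatrix-class].
#' @param reference character vector of reference ids (subset of the matrix
#'   ids); defaults to all ids in `K`.
#' @param includeSelf logical, include \eqn{f_{ii}} for reference members.
#' @return Named numeric vector of MK values for every id in `K`.
#' @export
meanKinship <- function(K, reference = kinshipIds(K), includeSelf = TRUE) {
  f <- kinshipValues(K)
  reference <- unique(reference)
  if (!length(reference)) stop("reference set is empty")
  missing <- setdiff(reference, rownames(f))
  if (length(missing))
    stop("reference id(s) not in kinship matrix: ",
         paste(missing, collapse = ", "))
  sums <- rowSums(f[, reference, drop = FALSE])
  if (includeSelf) return(sums / length(reference))
  inRef <- rownames(f) %in% reference
  if (any(inRef) && length(reference) == 1L)
    stop("cannot exclude the self term from a single-member reference")
  mk <- sums / length(reference)
  mk[inRef] <- (sums[inRef] - diag(f)[inRef]) / (length(reference) - 1L)
  mk
}

#' Colour-code mean kinship values for breeding advice
#'
#' Partitions animals into three groups by MK: `green` below the lower
#' threshold (relatively unrelated, preferred breeders), `yellow` inside
#' the closed interval, and `orange` above the upper threshold.  Defaults
#' are the published 0.31 / 0.32 cutpoints; boundary values fall in yellow.
#'
#' @param mk numeric vector of MK values in `[0, 1]`.
#' @param lower,upper thresholds; green iff `mk < lower`, orange iff
#'   `mk > upper`, yellow otherwise.
#' @return factor with levels `green`, `yellow`, `orange` (names kept).
#' @examples
#' mkColorGroups(c(a = 0.305, b = 0.31, c = 0.325))
#' @export
mkColorGroups <- function(mk, lower = 0.31, upper = 0.32) {
  if (any(mk < 0 | mk > 1, na.rm = TRUE))
    stop("MK values must lie in [0, 1]")
  g <- ifelse(mk < lower, "green", ifelse(mk > upper, "orange", "yellow"))
  factor(setNames(g, names(mk)), levels = c("green", "yellow", "orange"))
}
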