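#' Heteroplasmy fraction of a mitochondrial variant
#'
#' Percentage of sequencing reads supporting the alternative allele at an
#' mtDNA position; 100% is homoplasmy.  The raw percentage is returned;
#' round to integer percent only for presentation.
#'
#' @param depthAlt,depthTotal read depths (alt-supporting and total);
#'   vectorised.
#' @return numeric percentage(s) in `[0, 100]`.
#' @examples
#' heteroplasmy(96, 100)  # 96
#' @export
heteroplasmy <- function(depthAlt, depthTotal) {
  if (any(depthTotal <= 0)) stop("depthTotal must be positive")
  if (any(depthAlt < 0)) stop("depthAlt must be non-negative")
  if (any(depthAlt > depthTotal)) stop("depthAlt exceeds depthTotal")
  100 * depthAlt / depthTotal
}

#' Read per-sample mitochondrial variant calls
#'
#' TSV with columns `sample`, `pos`, `ref`, `alt`, `gene`, `depth_alt`,
#' `depth_total`; lines starting with `#` are comments.
#'
#' @param path file path.
#' @return data.frame of the calls.
#' @export
readMtVariants <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                  stringsAsFactors = FALSE)
  need <- c("sample", "pos", "ref", "alt")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  x
}

#' Read a haplogroup definition table
#'
#' TSV with columns `label`, `parent` (empty for the root) and `variants`,
#' a comma-separated list of `pos:alt` tokens defining the haplogroup in
#' addition to its ancestors' variants.  The definitions must form a tree
#' with a single root.
#'
#' @param path file path.
#' @return data.frame with `label`, `parent`, and list-column `variants`.
#' @export
readHaplogroupDefs <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                  stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("label", "parent", "variants")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  x$variants <- lapply(x$variants, function(v) {
    if (is.na(v) || !nzchar(v)) character(0)
    else trimws(strsplit(v, ",")[[1]])
  })
  validateHaplogroupDefs(x)
  x
}

validateHaplogroupDefs <- function(defs) {
  if (anyDuplicated(defs$label)) stop("duplicated haplogroup labels")
  roots <- defs$label[is.na(defs$parent)]
  if (length(roots) != 1)
    stop("definitions must have exactly one root (found ",
         length(roots), ")")
  known <- defs$parent[!is.na(defs$parent)]
  miss <- setdiff(known, defs$label)
  if (length(miss)) stop("unknown parent label(s): ",
                         paste(miss, collapse = ", "))
  # acyclicity: every label must reach the root
  for (lab in defs$label) {
    seen <- character(0)
    cur <- lab
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cycle in haplogroup definitions at ", cur)
      seen <- c(seen, cur)
      cur <- defs$parent[match(cur, defs$label)]
    }
  }
  invisible(defs)
}

haplogroupChain <- function(defs, label) {
  chain <- character(0)
  cur <- label
  while (!is.na(cur)) {
    chain <- c(chain, cur)
    cur <- defs$parent[match(cur, defs$label)]
  }
  chain  # label first, root last
}

#' Assign an mtDNA haplogroup from a definition tree
#'
#' Returns the deepest haplogroup whose full defining-variant set (its own
#' plus all of its ancestors') is contained in the sample's variants.  A
#' sample matching nothing beyond the root is assigned the root label.
#' Non-defining extra variants never change the call.
#'
#' @param sampleVariants character vector of `pos:alt` tokens carried by
#'   the sample (or a data.frame with `pos` and `alt` columns).
#' @param defs definition table from [readHaplogroupDefs()].
#' @return the haplogroup label.
#' @export
assignHaplogroup <- function(sampleVariants, defs) {
  validateHaplogroupDefs(defs)
  if (is.data.frame(sampleVariants))
    sampleVariants <- paste0(sampleVariants$pos, ":", sampleVariants$alt)
  depths <- vapply(defs$label,
                   function(l) length(haplogroupChain(defs, l)), integer(1))
  fullSet <- lapply(defs$label, function(l) {
    unique(unlist(defs$variants[match(haplogroupChain(defs, l), defs$label)]))
  })
  matches <- vapply(fullSet, function(s) all(s %in% sampleVariants),
                    logical(1))
  if (!any(matches)) return(defs$label[is.na(defs$parent)])
  best <- max(depths[matches])
  cand <- defs$label[matches & depths == best]
  if (length(cand) > 1)
    stop("ambiguous haplogroup assignment; equally deep matches: ",
         paste(cand, collapse = ", "))
  cand
}

#' Assign haplogroups for every sample of a variant table
#'
#' @param mtVariants data.frame from [readMtVariants()].
#' @param defs definition table from [readHaplogroupDefs()].
#' @return data.frame with `sample` and `haplogroup`.
#' @export
assignHaplogroups <- function(mtVariants, defs) {
  samples <- unique(mtVariants$sample)
  labels <- vapply(samples, function(s) {
    v <- mtVariants[mtVariants$sample == s, ]
    assignHaplogroup(paste0(v$pos, ":", v$alt), defs)
  }, character(1))
  data.frame(sample = samples, haplogroup = labels, row.names = NULL)
}
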