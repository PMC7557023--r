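#' Identity-by-state genetic distance
#'
#' For each pair of individuals, the mean over jointly non-missing SNPs of
#' the shared-allele fraction (1 for identical genotypes, 0.5 when one
#' allele is shared, 0 for opposite homozygotes), subtracted from 1.  With
#' dosage coding this is `mean(|g_i - g_j|) / 2`.
#'
#' @param g a [GenotypeMatrix-class] with at least two individuals.
#' @return symmetric distance matrix with zero diagonal.
#' @export
ibsDistance <- function(g) {
  calls <- genotypeCalls(g)
  n <- ncol(calls)
  if (n < 2) stop("at least two individuals are required")
  D <- matrix(0, n, n, dimnames = list(colnames(calls), colnames(calls)))
  for (i in seq_len(n - 1)) {
    xi <- calls[, i]
    for (j in seq(i + 1, n)) {
      xj <- calls[, j]
      ok <- !is.na(xi) & !is.na(xj)
      if (!any(ok))
        stop("no jointly genotyped SNPs for pair ", colnames(calls)[i],
             " / ", colnames(calls)[j])
      D[i, j] <- D[j, i] <- mean(abs(xi[ok] - xj[ok])) / 2
    }
  }
  D
}

#' Classical (metric) multidimensional scaling
#'
#' Torgerson scaling of a distance matrix: double-centre the squared
#' distances, eigendecompose, and return the top-`k` coordinates scaled by
#' the square roots of the eigenvalues (via [stats::cmdscale]).  For
#' distances that are exactly Euclidean the embedding reproduces them.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param k number of dimensions to return; must not exceed the number of
#'   positive eigenvalues.
#' @return list with `coordinates` (n x k matrix, column means zero) and
#'   `eigenvalues` (all n, non-increasing; negative ones reported, unused).
#' @export
classicalMds <- function(D, k = 2) {
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)) ||
      any(abs(diag(D)) > 1e-12))
    stop("D must be symmetric with a zero diagonal")
  fit <- suppressWarnings(cmdscale(D, k = nrow(D) - 1, eig = TRUE))
  eig <- fit$eig
  nPos <- sum(eig > max(abs(eig)) * 1e-9)
  if (k > nPos)
    stop("k = ", k, " exceeds the number of positive eigenvalues (", nPos, ")")
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("C", seq_len(k))
  list(coordinates = coords, eigenvalues = sort(eig, decreasing = TRUE))
}
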