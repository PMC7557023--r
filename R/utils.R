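# internal helpers shared across modules

# Run code with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Order chromosome labels numerically where possible (1..38 before X, Y, MT).
chromOrder <- function(chrom) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.integer(chrom))
  order(is.na(num), num, chrom)
}

isAutosome <- function(chrom, autosomes = as.character(1:38)) {
  as.character(chrom) %in% as.character(autosomes)
}

writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
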