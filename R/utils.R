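# shared helpers: canonical leaf-set keys and seed derivation

#' Canonical key for a set of species
#'
#' Branch identity throughout the package is a descendant leaf set, encoded
#' as the sorted, comma-joined species names. Keys are stable across trees
#' and prunings, unlike node numbers.
#'
#' @param species character vector of species names.
#' @return single string key.
#' @export
leafSetKey <- function(species) paste(sort(unique(as.character(species))), collapse = ",")

#' @noRd
keyToSpecies <- function(key) strsplit(key, ",", fixed = TRUE)[[1]]

# Derive reproducible per-unit seeds from one master seed; kept below 2^31.
#' @noRd
deriveSeeds <- function(masterSeed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(masterSeed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' @noRd
emptyBranchMetrics <- function() {
  data.frame(key = character(), t = numeric(), dnds = numeric(),
             dn = numeric(), ds = numeric(), stringsAsFactors = FALSE)
}

#' @noRd
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @noRd
readTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
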