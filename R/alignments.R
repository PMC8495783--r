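# Reading, validating and screening per-gene coding alignments.

#' Construct a codon alignment
#'
#' @param geneId gene identifier.
#' @param sequences named character vector or [Biostrings::DNAStringSet] of
#'   aligned in-frame nucleotide sequences (species names as names).
#' @return a [CodonAlignment-class] object.
#' @examples
#' codonAlignment("g1", c(A = "ATGAAA", B = "ATGAAG"))
#' @export
codonAlignment <- function(geneId, sequences) {
  if (!is(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
    names(sequences) <- nm
  }
  new("CodonAlignment", geneId = as.character(geneId), sequences = sequences)
}

#' Retrieve a genetic code table
#'
#' Wraps the NCBI translation tables shipped with Biostrings. The default is
#' table 1 (the standard code); the screening step accepts any table id.
#'
#' @param tableId NCBI translation table number (default 1).
#' @return a [GeneticCode-class] object.
#' @export
geneticCode <- function(tableId = 1L) {
  map <- Biostrings::getGeneticCode(as.character(tableId))
  new("GeneticCode", tableId = as.integer(tableId),
      codonMap = map, stopCodons = names(map)[map == "*"])
}

#' Read a folder of per-gene FASTA alignments
#'
#' One alignment per file; the gene id is the file stem. Files that fail to
#' parse or violate alignment invariants (unequal lengths, length not
#' divisible by 3, bad alphabet, duplicate names) are reported in the
#' exclusion table, never fatal to the batch. An empty directory is an error.
#'
#' @param dir directory containing FASTA files.
#' @param extensions file extensions recognized as alignments.
#' @return list with `alignments` (list of [CodonAlignment-class], named by
#'   gene id) and `excluded` (data.frame `gene_id`, `reason`).
#' @export
readGeneAlignments <- function(dir, extensions = c("fas", "fasta", "fa")) {
  if (!dir.exists(dir)) stop("alignment directory does not exist: ", dir)
  pat <- paste0("\\.(", paste(extensions, collapse = "|"), ")$")
  files <- sort(list.files(dir, pattern = pat, full.names = TRUE))
  if (length(files) == 0L)
    stop("no alignment files (", paste0(".", extensions, collapse = "/"), ") in ", dir)
  alns <- list()
  excluded <- data.frame(gene_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (f in files) {
    gid <- tools::file_path_sans_ext(basename(f))
    res <- tryCatch({
      seqs <- Biostrings::readDNAStringSet(f)
      # strip FASTA descriptions after the first whitespace
      names(seqs) <- sub("\\s.*$", "", names(seqs))
      codonAlignment(gid, seqs)
    }, error = function(e) conditionMessage(e))
    if (is(res, "CodonAlignment")) {
      alns[[gid]] <- res
    } else {
      excluded <- rbind(excluded,
                        data.frame(gene_id = gid, reason = res, stringsAsFactors = FALSE))
    }
  }
  list(alignments = alns, excluded = excluded)
}

#' Write a codon alignment to FASTA
#'
#' @param aln a [CodonAlignment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGeneAlignment <- function(aln, path) {
  stopifnot(is(aln, "CodonAlignment"))
  Biostrings::writeXStringSet(aln@sequences, path, width = 20000L)
  invisible(path)
}

#' Screen an alignment for stop codons
#'
#' A gene fails the screen if any sequence contains a stop codon at a codon
#' boundary, terminal stops included (CodeML rejects them). Pure gap codons
#' (`---`) are skipped and codons containing `N` or partial gaps translate
#' as unknown, never as stops, so ambiguity cannot exclude a gene.
#'
#' @param aln a [CodonAlignment-class].
#' @param code a [GeneticCode-class] (default: standard code).
#' @return list with `pass` (logical) and `stops` (data.frame `species`,
#'   `codon_index`, `codon` of every stop found).
#' @examples
#' screenStopCodons(codonAlignment("g", c(s = "ATGTAA")))$pass  # FALSE
#' @export
screenStopCodons <- function(aln, code = geneticCode()) {
  stopifnot(is(aln, "CodonAlignment"), is(code, "GeneticCode"))
  hits <- list()
  for (sp in names(aln@sequences)) {
    s <- as.character(aln@sequences[[sp]])
    cods <- substring(s, seq(1L, nchar(s), by = 3L), seq(3L, nchar(s), by = 3L))
    isStop <- cods %in% code@stopCodons  # codons with N or '-' never match
    if (any(isStop)) {
      hits[[sp]] <- data.frame(species = sp, codon_index = which(isStop),
                               codon = cods[isStop], stringsAsFactors = FALSE)
    }
  }
  stops <- if (length(hits)) do.call(rbind, c(hits, make.row.names = FALSE)) else
    data.frame(species = character(), codon_index = integer(), codon = character(),
               stringsAsFactors = FALSE)
  list(pass = nrow(stops) == 0L, stops = stops)
}
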