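# Translate user clade/branch definitions into PAML-labeled trees, per gene,
# including on pruned trees.

#' Construct a clade definition
#'
#' @param name unique definition name.
#' @param species character vector of species in the branch/clade.
#' @param token PAML label token: `"#k"` for a branch rate (placed on the
#'   stem of the MRCA), `"$k"` for a clade rate (all branches of the
#'   subtree, CodeML clade semantics).
#' @return a [CladeDefinition-class].
#' @export
cladeDefinition <- function(name, species, token) {
  new("CladeDefinition", name = as.character(name),
      species = unique(as.character(species)), token = as.character(token))
}

#' Parse a label-scheme file
#'
#' The scheme is a three-column TSV without header: definition name, label
#' token (`#k` or `$k`), comma-separated species list. When a species tree
#' is supplied, species unknown to the tree are a fatal error naming the
#' offending line.
#'
#' @param input path to the TSV file, or its lines as a character vector.
#' @param speciesTree optional [Phylogeny-class] to validate species against.
#' @return a [LabelScheme-class].
#' @examples
#' parseLabelScheme("cladeX\t$1\tC,D,E")
#' @export
parseLabelScheme <- function(input, speciesTree = NULL) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input, warn = FALSE) else input
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("label scheme is empty")
  defs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L)
      stop("label scheme line ", i, ": expected 3 tab-separated fields, got ", length(f))
    if (!grepl("^[#$][0-9]+$", f[2]))
      stop("label scheme line ", i, ": malformed token '", f[2],
           "' (expected #k or $k)")
    sp <- trimws(strsplit(f[3], ",", fixed = TRUE)[[1]])
    sp <- sp[nzchar(sp)]
    if (length(sp) == 0L) stop("label scheme line ", i, ": empty species list")
    if (!is.null(speciesTree)) {
      unknown <- setdiff(sp, taxaOf(speciesTree))
      if (length(unknown))
        stop("label scheme line ", i, ": species not in species tree: ",
             paste(unknown, collapse = ", "))
    }
    defs[[i]] <- cladeDefinition(trimws(f[1]), sp, f[2])
  }
  new("LabelScheme", definitions = defs)
}

#' @rdname parseLabelScheme
#' @param scheme a [LabelScheme-class].
#' @param path output file path.
#' @export
writeLabelScheme <- function(scheme, path) {
  stopifnot(is(scheme, "LabelScheme"))
  lines <- vapply(scheme@definitions, function(d)
    paste(d@name, d@token, paste(d@species, collapse = ","), sep = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Most recent common ancestor of a species set
#'
#' Returns the ape node id of the node whose descendant leaf set is the
#' minimal superset of `species`; a single species maps to its own leaf.
#'
#' @param phylogeny a [Phylogeny-class].
#' @param species nonempty subset of the tree's leaves.
#' @return integer ape node id.
#' @export
mrcaNode <- function(phylogeny, species) {
  stopifnot(is(phylogeny, "Phylogeny"))
  species <- unique(as.character(species))
  if (length(species) == 0L) stop("species set must be nonempty")
  missing <- setdiff(species, taxaOf(phylogeny))
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  mrcaNodeId(phylogeny@tree, species)
}

#' Annotate a tree with a label scheme
#'
#' Places each definition's token on the MRCA of its species that are
#' present in this tree: `#` tokens mark the MRCA's stem branch, `$` tokens
#' the whole subtree (CodeML clade semantics). Definitions whose present
#' species are not monophyletic in this tree are still labeled at the MRCA
#' but flagged in the report; definitions with no species present are
#' skipped and recorded. Labels are re-derived from the surviving species,
#' so annotation works identically on pruned trees.
#'
#' @param phylogeny a [Phylogeny-class] (pre-existing labels are replaced).
#' @param scheme a [LabelScheme-class].
#' @return list with `phylogeny` (labeled [Phylogeny-class]) and `report`
#'   (data.frame `name`, `token`, `n_present`, `placed`, `monophyletic`).
#' @export
annotateTree <- function(phylogeny, scheme) {
  stopifnot(is(phylogeny, "Phylogeny"), is(scheme, "LabelScheme"))
  phy <- phylogeny@tree
  labels <- rep("", length(phy$tip.label) + phy$Nnode)
  desc <- nodeDescendants(phy)
  rows <- lapply(scheme@definitions, function(d) {
    present <- intersect(d@species, phy$tip.label)
    if (length(present) == 0L) {
      return(data.frame(name = d@name, token = d@token, n_present = 0L,
                        placed = FALSE, monophyletic = NA, stringsAsFactors = FALSE))
    }
    node <- mrcaNodeId(phy, present)
    mono <- setequal(desc[[node]], present)
    labels[node] <<- d@token
    data.frame(name = d@name, token = d@token, n_present = length(present),
               placed = TRUE, monophyletic = mono, stringsAsFactors = FALSE)
  })
  out <- new("Phylogeny", tree = phy, labels = labels, rooted = phylogeny@rooted)
  list(phylogeny = out, report = do.call(rbind, rows))
}
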