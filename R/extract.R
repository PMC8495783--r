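# The extract stage: identify equivalent branches/clades across per-gene
# (possibly taxon-incomplete) trees, apply missing-species thresholds, and
# assemble per-definition metric tables.

#' Build an extract configuration
#'
#' Mode A restricts to genes carrying every species of the branch/clade of
#' interest (missing species may only be external to it); mode B also
#' tolerates missing species inside it, up to a threshold. A threshold
#' below 1 is a proportion (a clade of size n requires
#' `ceiling(threshold * n)` species present — "at least" semantics); a
#' value >= 1 is an absolute count. The boundary value 1 is therefore an
#' absolute count of one; a full-presence requirement is written as mode A.
#'
#' @param mode `"A"` or `"B"`.
#' @param threshold mode-B presence threshold (ignored for mode A).
#' @return an [ExtractConfig-class].
#' @export
extractConfig <- function(mode = c("A", "B"), threshold = 0.8) {
  mode <- match.arg(mode)
  new("ExtractConfig", mode = mode, threshold = as.numeric(threshold))
}

#' Species sets of every branch of a tree
#'
#' Lists the descendant species of each branch (edge) of the phylogeny:
#' leaf branches give singletons, internal branches their full subtree.
#' Keys are canonical leaf-set keys (see [leafSetKey()]).
#'
#' @param phylogeny a [Phylogeny-class].
#' @return named list: key -> character vector of species (one per edge).
#' @export
enumerateBranchSpecies <- function(phylogeny) {
  stopifnot(is(phylogeny, "Phylogeny"))
  phy <- phylogeny@tree
  desc <- nodeDescendants(phy)
  sets <- desc[phy$edge[, 2]]
  setNames(sets, vapply(sets, leafSetKey, character(1)))
}

#' @noRd
requiredPresence <- function(cfg, defnSize) {
  if (cfg@mode == "A") return(defnSize)
  if (cfg@threshold < 1) ceiling(cfg@threshold * defnSize) else ceiling(cfg@threshold)
}

#' Match a branch/clade definition in one gene's tree
#'
#' Let `P` be the definition's species present in the gene. The definition
#' matches iff `P` meets the presence requirement (mode A: all of them;
#' mode B: at least the threshold) AND `P` is the exact descendant leaf set
#' of some edge of the gene tree (the equivalent branch/clade exists). A
#' `$` (clade) definition reduced to a single present species is unmatched —
#' no clade remains — while a `#` (branch) definition matches the terminal
#' branch. Unmatched reasons: `below-threshold`, `not-monophyletic`,
#' `clade-reduced-to-single-species-with-clade-token`.
#'
#' @param defn a [CladeDefinition-class].
#' @param geneTaxa species present in the gene (= gene-tree leaves).
#' @param geneTree the gene's [Phylogeny-class].
#' @param cfg an [ExtractConfig-class].
#' @return list: `gene_id` left to the caller; `matched` (logical),
#'   `present` (character), `matchedKey` (leaf-set key or `NA`), `reason`
#'   (`NA` when matched).
#' @export
matchDefinition <- function(defn, geneTaxa, geneTree, cfg) {
  stopifnot(is(defn, "CladeDefinition"), is(geneTree, "Phylogeny"),
            is(cfg, "ExtractConfig"))
  geneTaxa <- unique(as.character(geneTaxa))
  present <- intersect(defn@species, geneTaxa)
  unmatched <- function(reason) list(matched = FALSE, present = present,
                                     matchedKey = NA_character_, reason = reason)
  need <- requiredPresence(cfg, length(defn@species))
  if (cfg@mode == "A" && length(present) < length(defn@species))
    return(unmatched("below-threshold"))
  if (length(present) < need || length(present) == 0L)
    return(unmatched("below-threshold"))
  if (length(present) == 1L) {
    if (startsWith(defn@token, "$"))
      return(unmatched("clade-reduced-to-single-species-with-clade-token"))
    if (!present %in% taxaOf(geneTree)) return(unmatched("not-monophyletic"))
    return(list(matched = TRUE, present = present,
                matchedKey = leafSetKey(present), reason = NA_character_))
  }
  # the equivalent branch exists iff P is the exact leaf set of some edge:
  # the MRCA of P must subtend exactly P and must not be the root
  phy <- geneTree@tree
  if (!all(present %in% phy$tip.label)) return(unmatched("not-monophyletic"))
  node <- mrcaNodeId(phy, present)
  desc <- nodeDescendants(phy)
  root <- length(phy$tip.label) + 1L
  if (node == root || !setequal(desc[[node]], present))
    return(unmatched("not-monophyletic"))
  list(matched = TRUE, present = present,
       matchedKey = leafSetKey(present), reason = NA_character_)
}

#' Retrieve dN/dS, dN, dS rows for a matched definition
#'
#' For a `#` (branch) definition: the single row whose key equals the
#' matched leaf set (the stem branch). For a `$` (clade) definition: the
#' stem row, every row whose key is a subset of the matched set (the
#' branches inside the clade), and an unweighted-mean aggregate row marked
#' `derived-mean` (never a substitute for the per-branch rows). A fit
#' lacking the stem row (or any branch table at all) is reported as
#' metrics-missing rather than silently dropped.
#'
#' @param match a matched result from [matchDefinition()].
#' @param fit the gene's best-fit [ModelFit-class].
#' @param defn the [CladeDefinition-class] that was matched.
#' @return data.frame `gene_id`, `branch`, `scope` (`stem`, `within`,
#'   `derived-mean`), `dnds`, `dn`, `ds`; or `NULL` with attribute handled
#'   by the caller when metrics are missing.
#' @export
retrieveMetrics <- function(match, fit, defn) {
  stopifnot(isTRUE(match$matched), is(fit, "ModelFit"), is(defn, "CladeDefinition"))
  bm <- branchMetrics(fit)
  stemKey <- match$matchedKey
  if (nrow(bm) == 0L || !stemKey %in% bm$key) return(NULL)  # metrics-missing
  stem <- bm[bm$key == stemKey, , drop = FALSE][1, ]
  mk <- function(row, scope) data.frame(
    gene_id = geneId(fit), branch = row$key, scope = scope,
    dnds = row$dnds, dn = row$dn, ds = row$ds, stringsAsFactors = FALSE)
  if (startsWith(defn@token, "#")) return(mk(stem, "stem"))
  matchedSet <- keyToSpecies(stemKey)
  inside <- vapply(bm$key, function(k) {
    sp <- keyToSpecies(k)
    length(sp) < length(matchedSet) && all(sp %in% matchedSet)
  }, logical(1))
  rows <- rbind(mk(stem, "stem"),
                do.call(rbind, lapply(which(inside), function(i)
                  mk(bm[i, , drop = FALSE], "within"))))
  agg <- data.frame(gene_id = geneId(fit), branch = stemKey,
                    scope = "derived-mean",
                    dnds = mean(rows$dnds), dn = mean(rows$dn),
                    ds = mean(rows$ds), stringsAsFactors = FALSE)
  rbind(rows, agg)
}

#' Assemble per-definition extract tables
#'
#' For every definition, matches each gene's tree, retrieves the metrics of
#' matched genes from their best-fit model, and reports each unmatched or
#' metrics-missing gene explicitly in the coverage report.
#'
#' @param genes named list (by gene id), each element a list with `tree`
#'   (the gene's [Phylogeny-class]) and `fit` (best-fit [ModelFit-class]).
#' @param scheme a [LabelScheme-class] of the definitions of interest.
#' @param cfg an [ExtractConfig-class].
#' @return list with `tables` (named list of per-definition data.frames)
#'   and `coverage` (data.frame `definition`, `gene_id`, `status`,
#'   `n_present`, `reason`).
#' @export
buildExtractTables <- function(genes, scheme, cfg) {
  stopifnot(is(scheme, "LabelScheme"), is(cfg, "ExtractConfig"))
  if (length(scheme@definitions) == 0L) stop("no branch/clade definitions supplied")
  if (length(genes) == 0L) stop("no gene results to extract from")
  tables <- list()
  cov <- list()
  for (d in scheme@definitions) {
    rows <- list()
    for (gid in sort(names(genes))) {
      g <- genes[[gid]]
      m <- matchDefinition(d, taxaOf(g$tree), g$tree, cfg)
      if (!m$matched) {
        cov[[length(cov) + 1L]] <- data.frame(
          definition = d@name, gene_id = gid, status = "unmatched",
          n_present = length(m$present), reason = m$reason,
          stringsAsFactors = FALSE)
        next
      }
      met <- retrieveMetrics(m, g$fit, d)
      if (is.null(met)) {
        cov[[length(cov) + 1L]] <- data.frame(
          definition = d@name, gene_id = gid, status = "metrics-missing",
          n_present = length(m$present), reason = "stem branch absent from fit",
          stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- met
      cov[[length(cov) + 1L]] <- data.frame(
        definition = d@name, gene_id = gid, status = "matched",
        n_present = length(m$present), reason = NA_character_,
        stringsAsFactors = FALSE)
    }
    tables[[d@name]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene_id = character(), branch = character(), scope = character(),
                 dnds = numeric(), dn = numeric(), ds = numeric(),
                 stringsAsFactors = FALSE)
    rownames(tables[[d@name]]) <- NULL
  }
  list(tables = tables, coverage = do.call(rbind, cov))
}
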