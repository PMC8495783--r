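# Newick parsing/writing (including the PAML #k/$k label dialect), per-gene
# pruning, bipartition machinery and normalized Robinson-Foulds distances.
#
# Parsing and pruning delegate to ape; PAML label tokens are carried through
# ape's parser by a reversible sentinel-token transform (ape itself has no
# notion of rate-class labels).

.pamlToSentinel <- function(text) {
  text <- gsub("[ \t]*#([0-9]+)", "__PAMLH\\1__", text)
  gsub("[ \t]*\\$([0-9]+)", "__PAMLD\\1__", text)
}

.sentinelToToken <- function(x) {
  tok <- rep("", length(x))
  h <- regmatches(x, regexpr("__PAMLH([0-9]+)__", x))
  d <- regmatches(x, regexpr("__PAMLD([0-9]+)__", x))
  hi <- grepl("__PAMLH[0-9]+__", x)
  di <- grepl("__PAMLD[0-9]+__", x)
  tok[hi] <- sub("__PAMLH([0-9]+)__", "#\\1", h)
  tok[di] <- sub("__PAMLD([0-9]+)__", "$\\1", d)
  tok
}

.stripSentinel <- function(x) gsub("__PAML[HD][0-9]+__", "", x)

#' Parse a newick tree, PAML label dialect included
#'
#' Accepts standard newick with optional branch lengths, multifurcations,
#' and PAML rate-class tokens (`#k` on a branch, `$k` on a clade) placed
#' after a leaf name or after a closing parenthesis, optionally preceded by
#' whitespace and followed by a branch length. Tokens are captured on the
#' corresponding node, not discarded.
#'
#' @param text newick string (must end with `;`).
#' @return a [Phylogeny-class].
#' @examples
#' parseNewick("((A:0.1,B:0.2) #1:0.05,(C,D));")
#' @export
parseNewick <- function(text) {
  text <- trimws(text)
  depth <- cumsum(vapply(strsplit(text, "")[[1]],
                         function(ch) (ch == "(") - (ch == ")"), numeric(1)))
  if (any(depth < 0))
    stop("unbalanced parentheses: unmatched ')' at character ", which(depth < 0)[1])
  if (length(depth) && depth[length(depth)] != 0)
    stop("unbalanced parentheses: ", depth[length(depth)],
         " '(' left open at end of string")
  phy <- ape::read.tree(text = .pamlToSentinel(text))
  if (is.null(phy)) stop("newick string could not be parsed")
  nt <- length(phy$tip.label)
  labels <- rep("", nt + phy$Nnode)
  labels[seq_len(nt)] <- .sentinelToToken(phy$tip.label)
  phy$tip.label <- .stripSentinel(phy$tip.label)
  if (!is.null(phy$node.label)) {
    labels[nt + seq_len(phy$Nnode)] <- .sentinelToToken(phy$node.label)
    phy$node.label <- NULL
  }
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate leaf names: ", paste(dup, collapse = ", "))
  }
  new("Phylogeny", tree = phy, labels = labels, rooted = ape::is.rooted(phy))
}

#' Read a newick file
#'
#' @param path file containing a single newick tree.
#' @return a [Phylogeny-class].
#' @export
readNewick <- function(path) {
  parseNewick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Write a tree as newick, PAML label dialect included
#'
#' Label tokens are emitted as `" #k"` / `" $k"` immediately after the
#' subtree (or leaf name) and before any branch length, the placement the
#' PAML tree dialect expects.
#'
#' @param phylogeny a [Phylogeny-class].
#' @param path optional file path; when `NULL` the newick string is returned.
#' @return the newick string (invisibly when written to file).
#' @export
writeNewick <- function(phylogeny, path = NULL) {
  stopifnot(is(phylogeny, "Phylogeny"))
  phy <- phylogeny@tree
  nt <- length(phy$tip.label)
  lab <- phylogeny@labels
  sent <- ifelse(nzchar(lab),
                 paste0("__PAML", ifelse(substr(lab, 1, 1) == "#", "H", "D"),
                        sub("^[#$]", "", lab), "__"),
                 "")
  phy$tip.label <- paste0(phy$tip.label, sent[seq_len(nt)])
  phy$node.label <- sent[nt + seq_len(phy$Nnode)]
  out <- ape::write.tree(phy)
  out <- gsub("__PAMLH([0-9]+)__", " #\\1", out)
  out <- gsub("__PAMLD([0-9]+)__", " $\\1", out)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

# descendant tip labels for every node (index = ape node id)
#' @noRd
nodeDescendants <- function(phy) {
  nt <- length(phy$tip.label)
  nn <- nt + phy$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(nt)) desc[[i]] <- phy$tip.label[i]
  edges <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    u <- edges[k, 1]; v <- edges[k, 2]
    desc[[u]] <- c(desc[[u]], desc[[v]])
  }
  lapply(desc, sort)
}

#' Prune a tree to a taxon subset
#'
#' Removes all leaves outside `keep`, suppresses the resulting
#' unifurcations (summing their branch lengths so path lengths are
#' preserved) and keeps polytomies intact. PAML labels are re-placed at the
#' MRCA of each label's surviving descendant set; labels whose descendants
#' are all removed are dropped.
#'
#' @param phylogeny a [Phylogeny-class].
#' @param keep character vector of leaf names to retain (at least 2, all
#'   present in the tree).
#' @return the pruned [Phylogeny-class].
#' @export
pruneToTaxa <- function(phylogeny, keep) {
  stopifnot(is(phylogeny, "Phylogeny"))
  keep <- unique(as.character(keep))
  phy <- phylogeny@tree
  missing <- setdiff(keep, phy$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  if (length(keep) < 2L)
    stop("cannot prune to fewer than 2 taxa (got ", length(keep), ")")
  if (setequal(keep, phy$tip.label) && length(keep) == length(phy$tip.label)) {
    return(phylogeny)
  }
  pruned <- ape::keep.tip(phy, keep)
  nt2 <- length(pruned$tip.label)
  labels2 <- rep("", nt2 + pruned$Nnode)
  old <- phylogeny@labels
  if (any(nzchar(old))) {
    descOld <- nodeDescendants(phy)
    for (v in which(nzchar(old))) {
      surv <- intersect(descOld[[v]], keep)
      if (length(surv) == 0L) next
      node <- mrcaNodeId(pruned, surv)
      if (!nzchar(labels2[node])) labels2[node] <- old[v]
    }
  }
  new("Phylogeny", tree = pruned, labels = labels2, rooted = phylogeny@rooted)
}

# MRCA as an ape node id on a raw phylo (single species -> the tip itself)
#' @noRd
mrcaNodeId <- function(phy, species) {
  species <- unique(as.character(species))
  if (length(species) == 1L) return(match(species, phy$tip.label))
  ape::getMRCA(phy, species)
}

#' Nontrivial bipartitions of a tree
#'
#' Returns the unrooted split set: one canonical key per internal edge.
#' Each split is encoded by the side not containing the alphabetically
#' first leaf, as a sorted comma-joined key (see [leafSetKey()]). Trivial
#' splits (one leaf against the rest) are excluded, so star trees return an
#' empty set.
#'
#' @param phylogeny a [Phylogeny-class].
#' @return character vector of canonical split keys (possibly empty).
#' @export
bipartitions <- function(phylogeny) {
  stopifnot(is(phylogeny, "Phylogeny"))
  phy <- phylogeny@tree
  tips <- sort(phy$tip.label)
  n <- length(tips)
  if (n < 4L) return(character())
  ref <- tips[1L]
  desc <- nodeDescendants(phy)
  root <- length(phy$tip.label) + 1L
  keys <- character()
  for (v in seq_along(desc)) {
    if (v == root) next
    s <- desc[[v]]
    if (length(s) < 2L || length(s) > n - 2L) next
    if (ref %in% s) s <- setdiff(tips, s)
    keys <- c(keys, leafSetKey(s))
  }
  sort(unique(keys))
}

#' Robinson-Foulds distance between two trees
#'
#' Raw RF is the size of the symmetric difference of the two nontrivial
#' (unrooted) split sets; the normalized distance divides by the total
#' number of nontrivial splits in both trees, which handles multifurcating
#' trees gracefully, and is defined as 0 when both trees are stars.
#'
#' @param t1,t2 [Phylogeny-class] objects on the same leaf set.
#' @return list with `rf_raw` (integer) and `rf_normalized` (in \[0,1\]).
#' @examples
#' rfDistance(parseNewick("((A,B),(C,D));"), parseNewick("((A,C),(B,D));"))
#' @export
rfDistance <- function(t1, t2) {
  stopifnot(is(t1, "Phylogeny"), is(t2, "Phylogeny"))
  if (!setequal(taxaOf(t1), taxaOf(t2)))
    stop("leaf sets differ; prune the trees to a common taxon set first")
  s1 <- bipartitions(t1)
  s2 <- bipartitions(t2)
  raw <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  denom <- length(s1) + length(s2)
  list(rf_raw = as.integer(raw),
       rf_normalized = if (denom == 0L) 0 else raw / denom)
}
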