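# shared test helpers: random trees/alignments built in code, tiny fit
# constructors, and an independent random DNA generator

# random binary tree wrapped as a Phylogeny (uses the current RNG state)
randomPhylogeny <- function(n, tipNames = paste0("t", seq_len(n)),
                            brFun = function(k) runif(k, 0.05, 0.3)) {
  phy <- ape::rtree(n, tip.label = tipNames, br = brFun)
  new("Phylogeny", tree = phy, labels = rep("", n + phy$Nnode), rooted = TRUE)
}

# random in-frame alignment over A,C,G,T with optional gaps/Ns
randomAlignment <- function(geneId, species, nCodons,
                            alphabet = c("A", "C", "G", "T")) {
  seqs <- vapply(species, function(s)
    paste(sample(alphabet, 3 * nCodons, replace = TRUE), collapse = ""),
    character(1))
  codonAlignment(geneId, seqs)
}

makeFit <- function(gene = "g", tag = "general", lnl = -100, np = 2L,
                    bm = NULL, rep = 1L, startOmega = NA_real_) {
  if (is.null(bm))
    bm <- data.frame(key = character(), t = numeric(), dnds = numeric(),
                     dn = numeric(), ds = numeric(), stringsAsFactors = FALSE)
  new("ModelFit", geneId = gene, modelTag = tag, lnl = lnl, np = as.integer(np),
      branchMetrics = bm, replicateIndex = as.integer(rep),
      startOmega = startOmega)
}

# species of a clade strictly below the root (its stem branch exists)
nonRootClade <- function(phylogeny, minSize = 2L) {
  phy <- apeTree(phylogeny)
  nt <- length(phy$tip.label)
  root <- nt + 1L
  cand <- setdiff(which(tabulate(phy$edge[, 1], nt + phy$Nnode) > 0), root)
  sets <- lapply(cand, function(v) nodeDescendantsOf(phylogeny, v))
  sets <- sets[lengths(sets) >= minSize & lengths(sets) <= nt - 2L]
  sets[[sample.int(length(sets), 1)]]
}

nodeDescendantsOf <- function(phylogeny, node) {
  phy <- apeTree(phylogeny)
  nt <- length(phy$tip.label)
  if (node <= nt) phy$tip.label[node] else ape::extract.clade(phy, node)$tip.label
}

# brute-force matcher: enumerate every edge of the gene tree and test set
# equality and thresholds directly (independent of the MRCA-based route)
bruteForceMatch <- function(defn, geneTaxa, geneTree, cfg) {
  present <- intersect(defn@species, geneTaxa)
  n <- length(defn@species)
  need <- if (cfg@mode == "A") n
    else if (cfg@threshold < 1) ceiling(cfg@threshold * n) else ceiling(cfg@threshold)
  if (cfg@mode == "A" && length(present) < n) return(FALSE)
  if (length(present) < need || length(present) == 0L) return(FALSE)
  if (length(present) == 1L && startsWith(defn@token, "$")) return(FALSE)
  phy <- apeTree(geneTree)
  edgeSets <- lapply(phy$edge[, 2], function(v)
    phy$tip.label[phangorn::Descendants(phy, v, "tips")[[1]]])
  any(vapply(edgeSets, function(s) setequal(s, present), logical(1)))
}
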