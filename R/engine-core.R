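# Built-in Goldman-Yang codon-model backend: M0 (single omega) and branch
# models with labeled omega classes. The engine makes the whole pipeline
# runnable and testable without an external CodeML binary; it is a minimal
# backend (equal codon frequencies, standard code, fixed branch lengths),
# not a general CodeML replacement.

.engineCache <- new.env(parent = emptyenv())

# precomputed structure of the 61-state sense-codon space (standard code):
# codon strings, amino acids, one-nucleotide-difference mask, transition
# mask (the single differing position is A<->G or C<->T), nonsynonymy mask
#' @noRd
codonSetup <- function() {
  if (!is.null(.engineCache$setup)) return(.engineCache$setup)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  aa <- unname(gc[gc != "*"])
  n <- length(sense)  # 61
  m <- do.call(rbind, strsplit(sense, ""))
  diffs <- matrix(0L, n, n)
  tsAtDiff <- matrix(FALSE, n, n)
  for (k in 1:3) {
    d <- outer(m[, k], m[, k], "!=")
    diffs <- diffs + d
    pur <- m[, k] %in% c("A", "G")
    tsAtDiff <- tsAtDiff | (d & outer(pur, pur, "=="))
  }
  one <- diffs == 1L
  setup <- list(
    codons = sense, aa = aa, n = n,
    one = one,
    ts = one & tsAtDiff,
    nonsyn = one & outer(aa, aa, "!=")
  )
  .engineCache$setup <- setup
  setup
}

#' Codon-model parameters
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega named numeric vector of dN/dS per rate class; must contain
#'   `"background"`, plus one entry per label token used on the tree. A
#'   single unnamed value is taken as the background class.
#' @param codonFreqs equilibrium frequencies over the 61 sense codons
#'   (default: equal, 1/61).
#' @return a validated parameter list of class `CodonModelParams`.
#' @export
codonModelParams <- function(kappa = 2, omega = c(background = 0.2),
                             codonFreqs = rep(1 / 61, 61)) {
  if (is.null(names(omega)) && length(omega) == 1L) names(omega) <- "background"
  stopifnot(kappa > 0, all(omega >= 0), "background" %in% names(omega))
  if (length(codonFreqs) != 61L || any(codonFreqs < 0) ||
      abs(sum(codonFreqs) - 1) > 1e-12)
    stop("codonFreqs must be 61 nonnegative values summing to 1")
  structure(list(kappa = kappa, omega = omega, codonFreqs = codonFreqs),
            class = "CodonModelParams")
}

#' Goldman-Yang instantaneous rate matrix
#'
#' Builds the 61x61 generator: codons differing at more than one position do
#' not exchange directly; a single-position change has rate
#' `pi_j * kappa^[transition] * omega^[nonsynonymous]`. The matrix is scaled
#' so the expected substitution rate at equilibrium is 1 (branch lengths are
#' then expected substitutions per codon).
#'
#' @param kappa transition/transversion rate ratio.
#' @param omega dN/dS of the rate class the matrix is built for.
#' @param codonFreqs equilibrium codon frequencies (61, sum 1).
#' @return 61x61 generator matrix with rows summing to zero.
#' @export
buildRateMatrix <- function(kappa, omega, codonFreqs = rep(1 / 61, 61)) {
  s <- codonSetup()
  R <- matrix(0, s$n, s$n)
  R[s$one] <- 1
  R[s$ts] <- kappa
  R[s$nonsyn] <- R[s$nonsyn] * omega
  R <- sweep(R, 2, codonFreqs, "*")
  diag(R) <- -rowSums(R)
  scale <- -sum(codonFreqs * diag(R))
  if (scale <= 0) stop("degenerate rate matrix (zero expected rate)")
  R / scale
}

# eigendecomposition of a reversible generator in the pi-symmetrized basis
#' @noRd
eigenGenerator <- function(Q, codonFreqs) {
  sp <- sqrt(codonFreqs)
  S <- Q * outer(sp, 1 / sp)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(U = e$vectors, lambda = e$values, sp = sp)
}

#' @noRd
transitionProb <- function(ed, t) {
  W <- ed$U * rep(exp(ed$lambda * t), each = nrow(ed$U))
  P <- W %*% t(ed$U)
  P <- P * outer(1 / ed$sp, ed$sp)
  P[P < 0] <- 0
  P
}

# rate-class token of every edge: "#" labels class the stem branch of their
# node; "$" labels class the stem and all descendant branches (CodeML clade
# semantics), with a deeper "#"/"$" overriding for its own subtree/branch.
#' @noRd
edgeClassTokens <- function(phylogeny) {
  phy <- ape::reorder.phylo(phylogeny@tree, "cladewise")  # preorder edges
  labels <- phylogeny@labels
  nn <- length(phy$tip.label) + phy$Nnode
  dollar <- rep("", nn)
  root <- length(phy$tip.label) + 1L
  if (startsWith(labels[root], "$")) dollar[root] <- labels[root]
  cls <- character(nrow(phy$edge))
  for (k in seq_len(nrow(phy$edge))) {
    u <- phy$edge[k, 1]; v <- phy$edge[k, 2]
    dollar[v] <- if (startsWith(labels[v], "$")) labels[v] else dollar[u]
    cls[k] <- if (startsWith(labels[v], "#")) labels[v]
      else if (nzchar(dollar[v])) dollar[v]
      else "background"
  }
  list(edge = phy$edge, edge.length = phy$edge.length, classes = cls, phy = phy)
}

# map alignment to codon-index matrix (rows = species); NA = gap/ambiguous
#' @noRd
codonIndexMatrix <- function(aln) {
  s <- codonSetup()
  seqs <- as.character(aln@sequences)
  nc <- nCodons(aln)
  idx <- matrix(NA_integer_, length(seqs), nc, dimnames = list(names(seqs), NULL))
  starts <- seq(1L, by = 3L, length.out = nc)
  for (i in seq_along(seqs)) {
    cods <- substring(seqs[i], starts, starts + 2L)
    idx[i, ] <- match(cods, s$codons)  # stop/gap/N codons -> NA (missing data)
  }
  idx
}

# collapse alignment columns to unique site patterns
#' @noRd
compressPatterns <- function(idx) {
  if (ncol(idx) == 0L)
    return(list(patterns = idx, weights = integer()))
  keys <- apply(idx, 2, paste, collapse = ",")
  u <- !duplicated(keys)
  map <- match(keys, keys[u])
  list(patterns = idx[, u, drop = FALSE], weights = tabulate(map, sum(u)))
}

# one-time setup shared by every likelihood evaluation during a fit
#' @noRd
prepareLikelihood <- function(aln, phylogeny) {
  phy <- phylogeny@tree
  if (is.null(phy$edge.length)) stop("tree must carry branch lengths")
  if (!all(sort(taxaOf(aln)) == sort(phy$tip.label)))
    stop("alignment species and tree leaves differ")
  ec <- edgeClassTokens(phylogeny)
  idx <- codonIndexMatrix(aln)
  idx <- idx[match(ec$phy$tip.label, rownames(idx)), , drop = FALSE]
  cp <- compressPatterns(idx)
  po <- ape::reorder.phylo(ec$phy, "postorder")
  # carry edge classes over to the postorder edge ordering by matching rows
  key <- function(e) paste(e[, 1], e[, 2])
  classes <- ec$classes[match(key(po$edge), key(ec$phy$edge))]
  nt <- length(po$tip.label)
  leafMats <- vector("list", nt)
  npat <- length(cp$weights)
  s <- codonSetup()
  for (i in seq_len(nt)) {
    M <- matrix(0, s$n, npat)
    x <- cp$patterns[i, ]
    known <- !is.na(x)
    if (any(known)) M[cbind(x[known], which(known))] <- 1
    if (any(!known)) M[, !known] <- 1
    leafMats[[i]] <- M
  }
  list(edge = po$edge, len = po$edge.length, classes = classes,
       nTip = nt, nNode = po$Nnode, leafMats = leafMats,
       weights = cp$weights, npat = npat,
       classTokens = sort(unique(classes)))
}

#' @noRd
logLikPrepared <- function(prep, kappa, omega, codonFreqs = rep(1 / 61, 61)) {
  need <- prep$classTokens
  if (!all(need %in% names(omega)))
    stop("omega is missing classes: ",
         paste(setdiff(need, names(omega)), collapse = ", "))
  eds <- lapply(setNames(need, need), function(tok)
    eigenGenerator(buildRateMatrix(kappa, omega[[tok]], codonFreqs), codonFreqs))
  nn <- prep$nTip + prep$nNode
  L <- vector("list", nn)
  logScale <- 0
  for (k in seq_len(nrow(prep$edge))) {
    u <- prep$edge[k, 1]; v <- prep$edge[k, 2]
    P <- transitionProb(eds[[prep$classes[k]]], prep$len[k])
    Lv <- if (v <= prep$nTip) prep$leafMats[[v]] else L[[v]]
    contrib <- P %*% Lv
    L[[u]] <- if (is.null(L[[u]])) contrib else L[[u]] * contrib
    sc <- colSums(L[[u]])
    if (any(sc <= 0) || any(!is.finite(sc))) return(-Inf)
    L[[u]] <- L[[u]] / rep(sc, each = nrow(L[[u]]))
    logScale <- logScale + sum(prep$weights * log(sc))
  }
  root <- prep$nTip + 1L
  rootLik <- as.vector(codonFreqs %*% L[[root]])
  if (any(rootLik <= 0)) return(-Inf)
  sum(prep$weights * log(rootLik)) + logScale
}

#' Codon-model log-likelihood
#'
#' Felsenstein pruning over the 61 sense codons: unique site patterns are
#' collapsed, per-branch transition matrices are `exp(Q t)` computed by
#' eigendecomposition of the reversible generator in the pi-symmetrized
#' basis, and each branch uses the rate class assigned by the tree's PAML
#' labels (unlabeled branches are the `"background"` class). Codons
#' containing gaps, `N`, or stops contribute an all-ones conditional vector
#' (missing data). Branch lengths are taken from the tree as expected
#' substitutions per codon and are not re-optimized.
#'
#' @param aln a [CodonAlignment-class]; species must equal the tree leaves.
#' @param phylogeny a labeled [Phylogeny-class] with branch lengths.
#' @param params a [codonModelParams()] list.
#' @return the log-likelihood (scalar; `-Inf` for impossible data).
#' @export
codonLogLikelihood <- function(aln, phylogeny, params) {
  stopifnot(is(aln, "CodonAlignment"), is(phylogeny, "Phylogeny"),
            inherits(params, "CodonModelParams"))
  prep <- prepareLikelihood(aln, phylogeny)
  if (prep$npat == 0L) return(0)
  logLikPrepared(prep, params$kappa, params$omega, params$codonFreqs)
}
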