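# Codon-alignment simulator and CodeML-output emulator for the built-in
# engine; these power fixture generation and the mlc round-trip tests.

#' Simulate a codon alignment along a tree
#'
#' Draws the root codon from the equilibrium frequencies and propagates
#' states down the tree, sampling each child from the row of `exp(Q t)` for
#' its branch, with the branch's rate class taken from the tree's PAML
#' labels. Reproducible under `seed`.
#'
#' @param phylogeny a (possibly labeled) [Phylogeny-class] with branch
#'   lengths.
#' @param params a [codonModelParams()] list.
#' @param nCodons number of codons to simulate (0 gives an empty alignment).
#' @param geneId gene id for the resulting alignment.
#' @param seed optional integer seed.
#' @return a [CodonAlignment-class].
#' @export
simulateCodonAlignment <- function(phylogeny, params, nCodons,
                                   geneId = "simulated", seed = NULL) {
  stopifnot(is(phylogeny, "Phylogeny"), inherits(params, "CodonModelParams"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  s <- codonSetup()
  ec <- edgeClassTokens(phylogeny)
  phy <- ec$phy  # cladewise: parents precede children
  if (is.null(phy$edge.length)) stop("tree must carry branch lengths")
  nt <- length(phy$tip.label)
  nn <- nt + phy$Nnode
  if (nCodons == 0L) {
    empty <- setNames(rep("", nt), phy$tip.label)
    return(codonAlignment(geneId, empty))
  }
  # label tokens without an omega of their own evolve as background, so a
  # null (single-omega) truth can be simulated directly on a labeled tree
  omegaOf <- function(tok) if (tok %in% names(params$omega))
    params$omega[[tok]] else params$omega[["background"]]
  eds <- lapply(setNames(unique(ec$classes), unique(ec$classes)), function(tok)
    eigenGenerator(buildRateMatrix(params$kappa, omegaOf(tok),
                                   params$codonFreqs), params$codonFreqs))
  states <- matrix(NA_integer_, nn, nCodons)
  root <- nt + 1L
  states[root, ] <- sample.int(s$n, nCodons, replace = TRUE, prob = params$codonFreqs)
  for (k in seq_len(nrow(phy$edge))) {
    u <- phy$edge[k, 1]; v <- phy$edge[k, 2]
    P <- transitionProb(eds[[ec$classes[k]]], phy$edge.length[k])
    parent <- states[u, ]
    child <- integer(nCodons)
    for (st in unique(parent)) {
      w <- which(parent == st)
      child[w] <- sample.int(s$n, length(w), replace = TRUE, prob = P[st, ])
    }
    states[v, ] <- child
  }
  seqs <- vapply(seq_len(nt), function(i)
    paste(s$codons[states[i, ]], collapse = ""), character(1))
  codonAlignment(geneId, setNames(seqs, phy$tip.label))
}

# expected synonymous / nonsynonymous mutational-opportunity weights at
# omega = 1 for a given kappa; used to turn (t, omega) into dN and dS
#' @noRd
synNonsynWeights <- function(kappa, codonFreqs = rep(1 / 61, 61)) {
  s <- codonSetup()
  base <- matrix(0, s$n, s$n)
  base[s$one] <- 1
  base[s$ts] <- kappa
  base <- base * outer(codonFreqs, codonFreqs)
  A <- sum(base[s$nonsyn])            # nonsynonymous flux at omega = 1
  B <- sum(base[s$one & !s$nonsyn])   # synonymous flux
  list(A = A, B = B, pN = A / (A + B), pS = B / (A + B))
}

#' Emulate a CodeML main-output (mlc) file
#'
#' Produces text in the PAML mlc dialect for a fitted engine model: the
#' `lnL(ntime: ... np: ...)` line, the tree with CodeML node numbers, and a
#' per-branch table with `t`, `N`, `S`, `dN/dS`, `dN`, `dS`. Each branch's
#' dN/dS equals the omega of its rate class; dN and dS are derived from the
#' branch length and the model's synonymous/nonsynonymous mutational
#' opportunity, so that `dN/dS` is exactly `omega`. Node numbering follows
#' CodeML's convention: leaves `1..N` in sequence-file order, internal
#' nodes `N+1..` parent-first.
#'
#' @param fit an [EngineFit-class].
#' @param phylogeny the (labeled) [Phylogeny-class] the fit used.
#' @param geneId gene id echoed in the header.
#' @param nCodons codon count used for the `N`/`S` site columns.
#' @param taxaOrder sequence-file species order (default: tree tip order).
#' @return single string of mlc-dialect text.
#' @export
emulateCodemlOutput <- function(fit, phylogeny, geneId = "gene",
                                nCodons = 100L,
                                taxaOrder = phylogeny@tree$tip.label) {
  stopifnot(is(fit, "EngineFit"), is(phylogeny, "Phylogeny"))
  ec <- edgeClassTokens(phylogeny)
  phy <- ec$phy
  num <- codemlNumbering(phy, taxaOrder)
  w <- synNonsynWeights(fit@kappa, fit@codonFreqs)
  lens <- phy$edge.length
  if (is.null(lens)) lens <- rep(0, nrow(phy$edge))
  rows <- character(nrow(phy$edge))
  for (k in seq_len(nrow(phy$edge))) {
    u <- phy$edge[k, 1]; v <- phy$edge[k, 2]
    # classes the fit did not estimate (e.g. labels under M0) are background
    om <- if (ec$classes[k] %in% names(fit@omega)) fit@omega[[ec$classes[k]]]
      else fit@omega[["background"]]
    t <- lens[k]
    rhoN <- om * w$A / (om * w$A + w$B)
    dn <- t * rhoN / (3 * w$pN)
    ds <- t * (1 - rhoN) / (3 * w$pS)
    rows[k] <- sprintf("%4d..%-4d %9.6f %8.1f %8.1f %9.6f %9.6f %9.6f",
                       num$nodeToCode[u], num$nodeToCode[v], t,
                       3 * nCodons * w$pN, 3 * nCodons * w$pS, om, dn, ds)
  }
  numTree <- phy
  numTree$tip.label <- as.character(num$nodeToCode[seq_along(phy$tip.label)])
  numTree$edge.length <- NULL
  paste(c(
    sprintf("CODONML (engine emulation)  gene: %s", geneId),
    "",
    sprintf("lnL(ntime: %2d  np: %2d): %14.6f      +0.000000",
            nrow(phy$edge), fit@np, fit@lnl),
    "",
    "tree with node numbers:",
    ape::write.tree(numTree),
    "",
    sprintf("kappa = %.6f", fit@kappa),
    "",
    " branch           t        N        S    dN/dS        dN        dS",
    rows,
    ""
  ), collapse = "\n")
}
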