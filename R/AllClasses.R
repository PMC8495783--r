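setOldClass("phylo")

#' CodonAlignment: an in-frame coding alignment for one gene
#'
#' Holds the aligned nucleotide sequences of a single protein-coding gene,
#' keyed by species name. Sequences must be equal length, in frame (length
#' divisible by 3) and restricted to the alphabet `A,C,G,T,N,-`.
#'
#' @slot geneId single gene identifier (usually the file stem).
#' @slot sequences a [Biostrings::DNAStringSet] with unique species names.
#'
#' @export
setClass("CodonAlignment",
  representation(geneId = "character", sequences = "DNAStringSet"))

setValidity("CodonAlignment", function(object) {
  msg <- character()
  if (length(object@geneId) != 1L || !nzchar(object@geneId))
    msg <- c(msg, "geneId must be a single non-empty string")
  nm <- names(object@sequences)
  if (length(object@sequences) > 0L) {
    if (is.null(nm) || anyNA(nm) || any(!nzchar(nm)))
      msg <- c(msg, "all sequences must be named by species")
    if (anyDuplicated(nm)) msg <- c(msg, "species names must be unique")
    if (any(grepl("\\s", nm))) msg <- c(msg, "species names must not contain whitespace")
    w <- Biostrings::width(object@sequences)
    if (length(unique(w)) > 1L) msg <- c(msg, "sequences must all have equal length")
    if (w[1L] %% 3L != 0L) msg <- c(msg, "alignment length must be divisible by 3")
    chars <- unique(strsplit(paste(as.character(object@sequences), collapse = ""), "")[[1]])
    bad <- setdiff(chars, c("A", "C", "G", "T", "N", "-"))
    if (length(bad))
      msg <- c(msg, paste0("alphabet restricted to A,C,G,T,N,-; found: ",
                           paste(bad, collapse = ",")))
  }
  if (length(msg)) msg else TRUE
})

#' Phylogeny: a tree with optional PAML branch/clade labels
#'
#' Wraps an [ape::phylo] tree together with a per-node vector of PAML label
#' tokens (`"#k"` marks the stem branch of a node, `"$k"` marks the whole
#' clade below it, `""` means unlabeled). Multifurcations are permitted.
#'
#' @slot tree an `ape::phylo` object; branch lengths optional.
#' @slot labels character vector of length `Ntip + Nnode`, indexed by ape
#'   node id; `""` for unlabeled nodes.
#' @slot rooted logical; whether the input newick was treated as rooted.
#'
#' @export
setClass("Phylogeny",
  representation(tree = "phylo", labels = "character", rooted = "logical"))

setValidity("Phylogeny", function(object) {
  msg <- character()
  phy <- object@tree
  nn <- length(phy$tip.label) + phy$Nnode
  if (length(object@labels) != nn)
    msg <- c(msg, sprintf("labels must have length Ntip + Nnode = %d", nn))
  bad <- object@labels[nzchar(object@labels)]
  if (length(bad) && any(!grepl("^[#$][0-9]+$", bad)))
    msg <- c(msg, "label tokens must match ^[#$][0-9]+$")
  if (anyDuplicated(phy$tip.label))
    msg <- c(msg, "leaf names must be unique")
  if (length(msg)) msg else TRUE
})

#' CladeDefinition: a named branch or clade of interest
#'
#' A branch/clade of interest is defined extensionally by the set of species
#' that descend from it on the species tree, plus a PAML label token:
#' `"#k"` for a single (stem) branch rate, `"$k"` for a clade-wide rate.
#'
#' @slot name unique definition name.
#' @slot species nonempty character vector of species names.
#' @slot token label token matching `^[#$][0-9]+$`.
#'
#' @export
setClass("CladeDefinition",
  representation(name = "character", species = "character", token = "character"))

setValidity("CladeDefinition", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@species) < 1L) msg <- c(msg, "species set must be nonempty")
  if (anyDuplicated(object@species)) msg <- c(msg, "species must be unique")
  if (length(object@token) != 1L || !grepl("^[#$][0-9]+$", object@token))
    msg <- c(msg, "token must match ^[#$][0-9]+$ (e.g. \"#1\" or \"$2\")")
  if (length(msg)) msg else TRUE
})

#' LabelScheme: an ordered list of clade definitions
#'
#' @slot definitions list of [CladeDefinition-class] objects with unique
#'   names; tokens may repeat (several clades can share one rate class).
#'
#' @export
setClass("LabelScheme", representation(definitions = "list"))

setValidity("LabelScheme", function(object) {
  ok <- vapply(object@definitions, is, logical(1), class2 = "CladeDefinition")
  if (!all(ok)) return("all elements must be CladeDefinition objects")
  nms <- vapply(object@definitions, function(d) d@name, character(1))
  if (anyDuplicated(nms)) return("definition names must be unique")
  TRUE
})

#' GeneticCode: codon-to-amino-acid table used for stop-codon screening
#'
#' @slot tableId NCBI translation table number.
#' @slot codonMap named character vector over all 64 codons (`"*"` = stop).
#' @slot stopCodons nonempty character vector of stop codons.
#'
#' @export
setClass("GeneticCode",
  representation(tableId = "integer", codonMap = "character",
                 stopCodons = "character"))

setValidity("GeneticCode", function(object) {
  msg <- character()
  if (length(object@codonMap) != 64L) msg <- c(msg, "codonMap must cover all 64 codons")
  if (length(object@stopCodons) < 1L) msg <- c(msg, "stop-codon set must be nonempty")
  if (length(msg)) msg else TRUE
})

#' ModelFit: one parsed codon-model fit for a gene
#'
#' A single CodeML (or built-in engine) fit: the maximized log-likelihood,
#' free-parameter count, and per-branch metric rows. Branches are keyed by
#' their descendant leaf set (sorted, comma-joined) rather than by volatile
#' CodeML node numbers, so fits from differently pruned trees remain
#' comparable across genes.
#'
#' @slot geneId gene identifier.
#' @slot modelTag `"general"` or `"alternative"` (the alternative model is
#'   the restricted one, nested within the general).
#' @slot lnl maximized log-likelihood.
#' @slot np free-parameter count as reported by the fit.
#' @slot branchMetrics data.frame with columns `key` (descendant leaf-set
#'   key), `t`, `dnds`, `dn`, `ds`; zero rows when the output carries no
#'   branch table (e.g. site models).
#' @slot replicateIndex 1-based replicate index the fit came from.
#' @slot startOmega the random omega starting value of that replicate
#'   (`NA` when unknown, e.g. external outputs).
#'
#' @export
setClass("ModelFit",
  representation(geneId = "character", modelTag = "character",
                 lnl = "numeric", np = "integer",
                 branchMetrics = "data.frame",
                 replicateIndex = "integer", startOmega = "numeric"))

setValidity("ModelFit", function(object) {
  msg <- character()
  if (!is.finite(object@lnl)) msg <- c(msg, "lnl must be finite")
  if (object@np < 1L) msg <- c(msg, "np must be >= 1")
  if (object@replicateIndex < 1L) msg <- c(msg, "replicateIndex must be >= 1")
  need <- c("key", "t", "dnds", "dn", "ds")
  if (!all(need %in% names(object@branchMetrics)))
    msg <- c(msg, paste("branchMetrics must have columns:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ExtractConfig: matching policy of the extract stage
#'
#' Mode A keeps a gene for a definition only when every species of the
#' definition is present in the gene; mode B tolerates missing species
#' inside the branch/clade of interest, up to a threshold given either as a
#' proportion (values < 1) or an absolute count (values >= 1).
#'
#' @slot mode `"A"` or `"B"`.
#' @slot threshold for mode B: minimum presence, proportion in (0,1) or
#'   absolute count >= 1. Ignored in mode A.
#'
#' @export
setClass("ExtractConfig",
  representation(mode = "character", threshold = "numeric"))

setValidity("ExtractConfig", function(object) {
  msg <- character()
  if (!object@mode %in% c("A", "B")) msg <- c(msg, "mode must be \"A\" or \"B\"")
  if (object@mode == "B") {
    th <- object@threshold
    if (length(th) != 1L || !is.finite(th) || th <= 0)
      msg <- c(msg, "mode B threshold must be a single positive number")
  }
  if (length(msg)) msg else TRUE
})

#' EngineFit: a maximum-likelihood fit from the built-in codon engine
#'
#' @slot kappa fitted transition/transversion rate ratio.
#' @slot omega named numeric vector of fitted dN/dS per rate class
#'   (`"background"` plus any label tokens).
#' @slot codonFreqs equilibrium codon frequencies (61 sense codons).
#' @slot lnl maximized log-likelihood.
#' @slot np number of free parameters optimized (kappa + one omega per class).
#' @slot converged optimizer convergence flag.
#'
#' @export
setClass("EngineFit",
  representation(kappa = "numeric", omega = "numeric", codonFreqs = "numeric",
                 lnl = "numeric", np = "integer", converged = "logical"))

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment '%s': %d sequences x %d codons\n",
              object@geneId, length(object@sequences), nCodons(object)))
})

setMethod("show", "Phylogeny", function(object) {
  nl <- sum(nzchar(object@labels))
  cat(sprintf("Phylogeny: %d tips, %d internal nodes%s%s\n",
              length(object@tree$tip.label), object@tree$Nnode,
              if (nl) sprintf(", %d PAML label(s)", nl) else "",
              if (is.null(object@tree$edge.length)) ", no branch lengths" else ""))
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit '%s' [%s]: lnL = %.6f, np = %d, %d branch rows (replicate %d)\n",
              object@geneId, object@modelTag, object@lnl, object@np,
              nrow(object@branchMetrics), object@replicateIndex))
})

setMethod("show", "CladeDefinition", function(object) {
  cat(sprintf("CladeDefinition '%s' (%s): %s\n", object@name, object@token,
              paste(object@species, collapse = ",")))
})

setMethod("show", "LabelScheme", function(object) {
  cat(sprintf("LabelScheme with %d definition(s)\n", length(object@definitions)))
  for (d in object@definitions) show(d)
})

setMethod("show", "EngineFit", function(object) {
  cat(sprintf("EngineFit: lnL = %.6f, np = %d, kappa = %.4f, omega = [%s]%s\n",
              object@lnl, object@np, object@kappa,
              paste(sprintf("%s=%.4f", names(object@omega), object@omega), collapse = ", "),
              if (object@converged) "" else " (not converged)"))
})
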