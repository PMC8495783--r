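#' Accessors for phyloOmega classes
#'
#' Small accessor generics: `geneId()` returns the gene identifier of an
#' alignment or fit, `nCodons()` the codon count of an alignment, `taxaOf()`
#' the exact species set of an alignment or the tip set of a tree, `lnL()`
#' and `nFreeParams()` the fit statistics, `branchMetrics()` the per-branch
#' metric table, and `pamlLabels()` the per-node PAML label tokens.
#'
#' @param x object to access.
#' @return see the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname accessors
#' @export
setGeneric("nCodons", function(x) standardGeneric("nCodons"))

#' @rdname accessors
#' @export
setGeneric("taxaOf", function(x) standardGeneric("taxaOf"))

#' @rdname accessors
#' @export
setGeneric("lnL", function(x) standardGeneric("lnL"))

#' @rdname accessors
#' @export
setGeneric("nFreeParams", function(x) standardGeneric("nFreeParams"))

#' @rdname accessors
#' @export
setGeneric("branchMetrics", function(x) standardGeneric("branchMetrics"))

#' @rdname accessors
#' @export
setGeneric("pamlLabels", function(x) standardGeneric("pamlLabels"))

#' @rdname accessors
#' @export
setMethod("geneId", "CodonAlignment", function(x) x@geneId)

#' @rdname accessors
#' @export
setMethod("geneId", "ModelFit", function(x) x@geneId)

#' @rdname accessors
#' @export
setMethod("nCodons", "CodonAlignment", function(x) {
  if (length(x@sequences) == 0L) 0L else Biostrings::width(x@sequences)[1L] %/% 3L
})

#' @rdname accessors
#' @export
setMethod("taxaOf", "CodonAlignment", function(x) as.character(names(x@sequences)))

#' @rdname accessors
#' @export
setMethod("taxaOf", "Phylogeny", function(x) x@tree$tip.label)

#' @rdname accessors
#' @export
setMethod("lnL", "ModelFit", function(x) x@lnl)

#' @rdname accessors
#' @export
setMethod("lnL", "EngineFit", function(x) x@lnl)

#' @rdname accessors
#' @export
setMethod("nFreeParams", "ModelFit", function(x) x@np)

#' @rdname accessors
#' @export
setMethod("nFreeParams", "EngineFit", function(x) x@np)

#' @rdname accessors
#' @export
setMethod("branchMetrics", "ModelFit", function(x) x@branchMetrics)

#' @rdname accessors
#' @export
setMethod("pamlLabels", "Phylogeny", function(x) x@labels)

#' Extract the underlying ape tree
#'
#' @param x a [Phylogeny-class] object.
#' @return the wrapped [ape::phylo] object.
#' @export
setGeneric("apeTree", function(x) standardGeneric("apeTree"))

#' @rdname apeTree
#' @export
setMethod("apeTree", "Phylogeny", function(x) x@tree)
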