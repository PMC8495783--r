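# CodeML control-file rendering, mlc-output parsing keyed by descendant leaf
# sets, replicate runs with random omega starts, and the CodeML node
# numbering convention shared with the emulator.

# CodeML node numbering: leaves 1..N in sequence-file order, internal nodes
# N+1.. in parent-first (preorder) order. Returns the node<->number maps and
# descendant leaf sets of the given tree.
#' @noRd
codemlNumbering <- function(phy, taxaOrder = phy$tip.label) {
  nt <- length(phy$tip.label)
  if (!setequal(taxaOrder, phy$tip.label))
    stop("taxaOrder must be a permutation of the tree's leaves")
  nn <- nt + phy$Nnode
  nodeToCode <- integer(nn)
  nodeToCode[seq_len(nt)] <- match(phy$tip.label, taxaOrder)
  cw <- ape::reorder.phylo(phy, "cladewise")
  seen <- unique(as.vector(t(cw$edge)))
  internals <- seen[seen > nt]
  nodeToCode[internals] <- nt + seq_along(internals)
  codeToNode <- integer(nn)
  codeToNode[nodeToCode] <- seq_len(nn)
  parent <- integer(nn)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  list(nodeToCode = nodeToCode, codeToNode = codeToNode,
       parent = parent, desc = nodeDescendants(phy), nTip = nt)
}

#' Read a CodeML control-file template
#'
#' Control templates are standard CodeML `key = value` files. The values of
#' `seqfile`, `treefile`, `outfile` and `omega` are treated as placeholders
#' and substituted at render time; every other option (model, NSsites,
#' fix_omega, ...) is opaque pass-through. All four placeholder keys must be
#' present.
#'
#' @param input path to the control file, or its lines.
#' @return a `ControlTemplate` (named character vector of options, ordered).
#' @export
readControlTemplate <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input, warn = FALSE) else input
  lines <- sub("\\*.*$", "", lines)  # strip CodeML comments
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  opts <- setNames(vals, keys)
  missing <- setdiff(c("seqfile", "treefile", "outfile", "omega"), keys)
  if (length(missing))
    stop("control template missing placeholder option(s): ",
         paste(missing, collapse = ", "))
  structure(opts, class = "ControlTemplate")
}

#' Render a control file for one gene and one replicate
#'
#' @param template a `ControlTemplate` from [readControlTemplate()].
#' @param seqfile,treefile,outfile paths substituted into the template.
#' @param startOmega the replicate's omega starting value.
#' @return control-file text (single string).
#' @export
renderControl <- function(template, seqfile, treefile, outfile, startOmega) {
  stopifnot(inherits(template, "ControlTemplate"))
  opts <- unclass(template)
  opts[["seqfile"]] <- seqfile
  opts[["treefile"]] <- treefile
  opts[["outfile"]] <- outfile
  opts[["omega"]] <- format(startOmega, digits = 8)
  paste(sprintf("%s = %s", names(opts), opts), collapse = "\n")
}

#' @noRd
controlOption <- function(template, key, default = NA_character_) {
  if (key %in% names(template)) unname(unclass(template)[[key]]) else default
}

#' Draw random omega starting values
#'
#' Replicate starts are sampled uniformly in \[0.05, 2.0\] (bounded away
#' from the omega = 0 boundary), reproducibly under a seed.
#'
#' @param n number of replicates.
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used (the pipeline seeds it per gene).
#' @return numeric vector of length `n`.
#' @export
drawStartOmegas <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  runif(n, 0.05, 2.0)
}

#' Parse a CodeML main output (mlc)
#'
#' Extracts the log-likelihood and free-parameter count from the
#' `lnL(ntime: ... np: ...)` line, and — when a per-branch table is present —
#' each branch row `a..b`, resolving node number `b` to its descendant leaf
#' set via the CodeML numbering of the supplied tree. Branch metrics are
#' therefore keyed by leaf set, which is stable across differently pruned
#' per-gene trees; node numbers are used only transiently here. An output
#' without a branch table (e.g. a site model) yields a fit with zero branch
#' rows; an output without an lnL line is a parse error.
#'
#' @param text mlc text (single string or lines).
#' @param phylogeny the tree the run used (a [Phylogeny-class]).
#' @param geneId,modelTag metadata stored on the resulting fit.
#' @param taxaOrder sequence-file species order (default: tree tip order).
#' @return a [ModelFit-class].
#' @export
parseMlc <- function(text, phylogeny, geneId = "gene", modelTag = "general",
                     taxaOrder = phylogeny@tree$tip.label) {
  stopifnot(is(phylogeny, "Phylogeny"))
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  m <- regexec("lnL\\(ntime:\\s*([0-9]+)\\s+np:\\s*([0-9]+)\\)\\s*:\\s*([-+0-9.eE]+)",
               lines)
  hit <- which(vapply(m, function(x) x[1] != -1L, logical(1)))
  if (length(hit) == 0L) stop("no lnL line found in mlc text")
  g <- regmatches(lines[hit[1]], m[hit[1]])[[1]]
  np <- as.integer(g[3])
  lnl <- as.numeric(g[4])
  if (!is.finite(lnl)) stop("non-finite lnL in mlc text")

  bm <- emptyBranchMetrics()
  rowIdx <- grep("^\\s*[0-9]+\\.\\.[0-9]+(\\s+[-+0-9.eE]+)+\\s*$", lines)
  if (length(rowIdx)) {
    hdrIdx <- grep("branch", lines)
    hdrIdx <- hdrIdx[grepl("dN/dS|\\bw\\b", lines[hdrIdx])]
    cols <- c("t", "N", "S", "dN/dS", "dN", "dS")  # documented fallback order
    if (length(hdrIdx)) {
      hdr <- strsplit(trimws(lines[hdrIdx[1]]), "\\s+")[[1]]
      cols <- hdr[-1]
      cols[cols == "w"] <- "dN/dS"
    }
    num <- codemlNumbering(phylogeny@tree, taxaOrder)
    nn <- length(num$nodeToCode)
    rows <- lapply(rowIdx, function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      ab <- as.integer(strsplit(f[1], "..", fixed = TRUE)[[1]])
      vals <- suppressWarnings(as.numeric(f[-1]))
      names(vals) <- cols[seq_along(vals)]
      a <- ab[1]; b <- ab[2]
      if (b < 1L || b > nn || a < 1L || a > nn)
        stop("branch row '", f[1], "' uses node numbers outside the tree")
      node <- num$codeToNode[b]
      par <- num$parent[node]
      if (par == 0L || num$nodeToCode[par] != a)
        stop("branch table numbering inconsistent with the supplied tree at row '",
             f[1], "'")
      dnds <- if ("dN/dS" %in% names(vals)) vals[["dN/dS"]] else NA_real_
      data.frame(key = leafSetKey(num$desc[[node]]),
                 t = if ("t" %in% names(vals)) vals[["t"]] else NA_real_,
                 dnds = dnds,
                 dn = if ("dN" %in% names(vals)) vals[["dN"]] else NA_real_,
                 ds = if ("dS" %in% names(vals)) vals[["dS"]] else NA_real_,
                 stringsAsFactors = FALSE)
    })
    bm <- do.call(rbind, rows)
  }
  new("ModelFit", geneId = geneId, modelTag = modelTag, lnl = lnl, np = np,
      branchMetrics = bm, replicateIndex = 1L, startOmega = NA_real_)
}

#' Select the best replicate
#'
#' The replicate with the maximum log-likelihood wins; exact ties are broken
#' by the lowest replicate index, so results are invariant under replicate
#' reordering.
#'
#' @param fits list of [ModelFit-class] replicates of one model.
#' @return the selected [ModelFit-class].
#' @export
selectBestReplicate <- function(fits) {
  if (length(fits) == 0L) stop("no successful replicates")
  lnls <- vapply(fits, lnL, numeric(1))
  idx <- vapply(fits, function(f) f@replicateIndex, integer(1))
  best <- which(lnls == max(lnls))
  fits[[best[which.min(idx[best])]]]
}

# run one replicate through the built-in engine: render control (for the
# record), fit, emulate mlc, parse back. The mlc text is returned so the
# analyze stage can persist it for the extract stage.
#' @noRd
runEngineReplicate <- function(aln, phylogeny, template, modelTag,
                               repIndex, startOmega, workDir) {
  modelOpt <- suppressWarnings(as.integer(controlOption(template, "model", "0")))
  ns <- suppressWarnings(as.integer(controlOption(template, "NSsites", "0")))
  if (!is.na(ns) && ns != 0L)
    stop("built-in engine supports branch models only (NSsites = 0); ",
         "use backend = \"codeml\" for site models")
  engineModel <- if (!is.na(modelOpt) && modelOpt > 0L) "branch" else "M0"
  seqfile <- file.path(workDir, paste0(geneId(aln), ".fas"))
  treefile <- file.path(workDir, paste0(geneId(aln), ".nwk"))
  outfile <- file.path(workDir, sprintf("%s_%s_rep%d.mlc", geneId(aln), modelTag, repIndex))
  ctl <- renderControl(template, seqfile, treefile, outfile, startOmega)
  writeLines(ctl, file.path(workDir, sprintf("%s_%s_rep%d.ctl",
                                             geneId(aln), modelTag, repIndex)))
  fit <- fitCodonModel(aln, phylogeny, model = engineModel, startOmega = startOmega)
  mlc <- emulateCodemlOutput(fit, phylogeny, geneId = geneId(aln),
                             nCodons = nCodons(aln))
  writeLines(mlc, outfile)
  mf <- parseMlc(mlc, phylogeny, geneId = geneId(aln), modelTag = modelTag)
  mf@replicateIndex <- as.integer(repIndex)
  mf@startOmega <- startOmega
  list(fit = mf, mlcPath = outfile)
}

# run one replicate through an external codeml binary in an isolated
# directory (codeml writes fixed-name scratch files)
#' @noRd
runCodemlReplicate <- function(aln, phylogeny, template, modelTag,
                               repIndex, startOmega, workDir) {
  repDir <- file.path(workDir, sprintf("%s_%s_rep%d", geneId(aln), modelTag, repIndex))
  dir.create(repDir, recursive = TRUE, showWarnings = FALSE)
  seqfile <- file.path(repDir, "gene.fas")
  treefile <- file.path(repDir, "gene.nwk")
  outfile <- file.path(repDir, "out.mlc")
  writeGeneAlignment(aln, seqfile)
  writeNewick(phylogeny, treefile)
  ctlPath <- file.path(repDir, "codeml.ctl")
  writeLines(renderControl(template, seqfile, treefile, outfile, startOmega), ctlPath)
  status <- system2("codeml", args = basename(ctlPath), stdout = FALSE,
                    stderr = FALSE, wait = TRUE,
                    env = character())
  if (!file.exists(outfile))
    stop("codeml produced no output (exit status ", status, ")")
  mf <- parseMlc(readLines(outfile, warn = FALSE), phylogeny,
                 geneId = geneId(aln), modelTag = modelTag)
  mf@replicateIndex <- as.integer(repIndex)
  mf@startOmega <- startOmega
  list(fit = mf, mlcPath = outfile)
}

#' Run the paired nested-model fits for one gene
#'
#' Fits the general and the alternative (restricted) model `nReplicates`
#' times each, every replicate starting from its own random omega drawn
#' uniformly in \[0.05, 2.0\] from the current RNG state, and returns the
#' best replicate per model. With `backend = "engine"` fits run through the
#' built-in Goldman-Yang engine and an emulated mlc is written per
#' replicate; with `backend = "codeml"` the external binary is invoked in
#' isolated per-replicate directories. Failed replicates are logged and
#' dropped; a model with no surviving replicate is an error (the batch
#' caller marks the gene failed).
#'
#' @param aln a [CodonAlignment-class] (species must equal the tree leaves).
#' @param phylogeny the labeled, pruned [Phylogeny-class] for this gene.
#' @param templates list with elements `general` and `alternative`, each a
#'   `ControlTemplate`.
#' @param nReplicates replicate count (>= 1).
#' @param backend `"engine"` or `"codeml"`.
#' @param workDir directory for control files and mlc outputs.
#' @return list with `general` and `alternative` (best [ModelFit-class]
#'   each), `replicateLog` (data.frame `gene`, `model`, `replicate`,
#'   `start_omega`, `lnl`, `status`) and `mlcPaths` (best replicate's mlc
#'   per model).
#' @export
runGene <- function(aln, phylogeny, templates, nReplicates = 1L,
                    backend = c("engine", "codeml"),
                    workDir = tempfile("rungene")) {
  backend <- match.arg(backend)
  stopifnot(all(c("general", "alternative") %in% names(templates)),
            nReplicates >= 1L)
  dir.create(workDir, recursive = TRUE, showWarnings = FALSE)
  writeGeneAlignment(aln, file.path(workDir, paste0(geneId(aln), ".fas")))
  writeNewick(phylogeny, file.path(workDir, paste0(geneId(aln), ".nwk")))
  runRep <- if (backend == "engine") runEngineReplicate else runCodemlReplicate
  log <- list()
  best <- list()
  mlcPaths <- list()
  for (tag in c("general", "alternative")) {
    omegas <- drawStartOmegas(nReplicates)
    fits <- list()
    paths <- character()
    for (i in seq_len(nReplicates)) {
      res <- tryCatch(
        runRep(aln, phylogeny, templates[[tag]], tag, i, omegas[i], workDir),
        error = function(e) conditionMessage(e))
      if (is.list(res)) {
        fits[[length(fits) + 1L]] <- res$fit
        paths[length(paths) + 1L] <- res$mlcPath
        log[[length(log) + 1L]] <- data.frame(
          gene = geneId(aln), model = tag, replicate = i,
          start_omega = omegas[i], lnl = lnL(res$fit), status = "ok",
          stringsAsFactors = FALSE)
      } else {
        log[[length(log) + 1L]] <- data.frame(
          gene = geneId(aln), model = tag, replicate = i,
          start_omega = omegas[i], lnl = NA_real_, status = res,
          stringsAsFactors = FALSE)
      }
    }
    if (length(fits) == 0L)
      stop("all ", nReplicates, " replicate(s) of the ", tag,
           " model failed for gene ", geneId(aln))
    sel <- selectBestReplicate(fits)
    best[[tag]] <- sel
    mlcPaths[[tag]] <- paths[[which(vapply(fits, function(f)
      f@replicateIndex, integer(1)) == sel@replicateIndex)]]
  }
  list(general = best$general, alternative = best$alternative,
       replicateLog = do.call(rbind, log), mlcPaths = mlcPaths)
}
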