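# The two user-facing stages (analyze, extract), the RF discordance report,
# and the synthetic fixture generator. Genes are independent work units;
# outputs are sorted by gene id and all randomness flows from one master
# seed through per-gene derived seeds, so results do not depend on
# scheduling order.

#' @noRd
asPhylogeny <- function(x) {
  if (is(x, "Phylogeny")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) return(readNewick(x))
  stop("expected a Phylogeny or a newick file path")
}

#' @noRd
asLabelScheme <- function(x, speciesTree = NULL) {
  if (is.null(x) || is(x, "LabelScheme")) return(x)
  parseLabelScheme(x, speciesTree)
}

#' @noRd
asTemplate <- function(x) {
  if (inherits(x, "ControlTemplate")) x else readControlTemplate(x)
}

#' Analyze stage: paired nested codon-model fits per gene
#'
#' Runs the full per-gene pipeline: read and validate alignments, screen
#' for stop codons (genes containing any are excluded), prune the species
#' tree to each gene's taxon set (or use per-gene trees), re-derive PAML
#' labels on the pruned tree, fit the general and alternative models with
#' replicate random omega starts, and summarize the LRTs with FDR
#' correction. Per-gene failures are logged and skipped, never fatal to the
#' batch. With `backend = "engine"` and a fixed seed the outputs are fully
#' deterministic.
#'
#' Outputs written under `outDir`: `summary.tsv` (LRT table),
#' `replicates.tsv`, `exclusions.tsv`, `labels_report.tsv` (when a scheme is
#' given), `rf_distances.tsv` (fixed-tree mode with gene trees available),
#' and per gene `genes/<id>/{general.mlc, alternative.mlc, tree.nwk}`.
#'
#' @param alignmentDir folder of per-gene FASTA alignments.
#' @param outDir output directory (created if needed).
#' @param generalTemplate,alternativeTemplate CodeML control templates
#'   (paths or [readControlTemplate()] objects); the alternative model must
#'   be nested in the general one.
#' @param speciesTree fixed species tree (path or [Phylogeny-class]); must
#'   contain every species seen in the alignments. Omit to run in per-gene
#'   tree mode.
#' @param geneTreeDir folder of per-gene newick trees named `<gene>.nwk`.
#'   With a species tree this only feeds the RF discordance report; without
#'   one it supplies the analysis trees.
#' @param labelScheme optional label scheme (path or [LabelScheme-class]).
#' @param nReplicates replicates per model per gene.
#' @param minTaxa genes with fewer taxa after screening are skipped.
#' @param alpha FDR significance level for best-model selection.
#' @param ubiquitousOnly drop genes not found in every species-tree species.
#' @param backend `"engine"` (built-in) or `"codeml"` (external binary).
#' @param seed master seed; per-gene seeds are derived from it.
#' @return invisibly, a list with `summary`, `exclusions`, `replicateLog`,
#'   `rf`, `labelsReport` and `outDir`.
#' @export
analyzeGenes <- function(alignmentDir, outDir,
                         generalTemplate, alternativeTemplate,
                         speciesTree = NULL, geneTreeDir = NULL,
                         labelScheme = NULL,
                         nReplicates = 2L, minTaxa = 4L, alpha = 0.05,
                         ubiquitousOnly = FALSE,
                         backend = c("engine", "codeml"), seed = 1L) {
  backend <- match.arg(backend)
  if (is.null(speciesTree) && is.null(geneTreeDir))
    stop("supply a species tree (fixed-tree mode) or a gene-tree folder")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sp <- if (!is.null(speciesTree)) asPhylogeny(speciesTree) else NULL
  scheme <- asLabelScheme(labelScheme, sp)
  templates <- list(general = asTemplate(generalTemplate),
                    alternative = asTemplate(alternativeTemplate))
  rd <- readGeneAlignments(alignmentDir)
  exclusions <- rd$excluded
  alns <- rd$alignments
  code <- geneticCode()

  keep <- list()
  for (gid in sort(names(alns))) {
    aln <- alns[[gid]]
    scr <- screenStopCodons(aln, code)
    if (!scr$pass) {
      exclusions <- rbind(exclusions, data.frame(
        gene_id = gid,
        reason = sprintf("stop_codon (%s at codon %d)",
                         scr$stops$species[1], scr$stops$codon_index[1]),
        stringsAsFactors = FALSE))
      next
    }
    if (length(taxaOf(aln)) < minTaxa) {
      exclusions <- rbind(exclusions, data.frame(
        gene_id = gid, reason = sprintf("too_few_taxa (%d < %d)",
                                        length(taxaOf(aln)), minTaxa),
        stringsAsFactors = FALSE))
      next
    }
    if (!is.null(sp)) {
      missing <- setdiff(taxaOf(aln), taxaOf(sp))
      if (length(missing)) {
        exclusions <- rbind(exclusions, data.frame(
          gene_id = gid, reason = paste0("species_missing_from_tree (",
                                         paste(missing, collapse = ","), ")"),
          stringsAsFactors = FALSE))
        next
      }
      if (ubiquitousOnly && !setequal(taxaOf(aln), taxaOf(sp))) {
        exclusions <- rbind(exclusions, data.frame(
          gene_id = gid, reason = "nonubiquitous", stringsAsFactors = FALSE))
        next
      }
    }
    keep[[gid]] <- aln
  }

  gids <- sort(names(keep))
  geneSeeds <- if (length(gids)) deriveSeeds(seed, length(gids)) else integer()
  lrtRows <- list()
  repLogs <- list()
  labRows <- list()
  rfRows <- list()
  for (i in seq_along(gids)) {
    gid <- gids[i]
    aln <- keep[[gid]]
    res <- tryCatch({
      tree <- if (!is.null(sp)) {
        pruneToTaxa(sp, taxaOf(aln))
      } else {
        gt <- file.path(geneTreeDir, paste0(gid, ".nwk"))
        if (!file.exists(gt)) stop("no gene tree file: ", gt)
        t <- readNewick(gt)
        if (!setequal(taxaOf(t), taxaOf(aln)))
          stop("gene tree leaves differ from alignment species")
        t
      }
      if (!is.null(scheme)) {
        ann <- annotateTree(tree, scheme)
        tree <- ann$phylogeny
        labRows[[gid]] <- cbind(gene_id = gid, ann$report)
      }
      geneDir <- file.path(outDir, "genes", gid)
      dir.create(geneDir, recursive = TRUE, showWarnings = FALSE)
      set.seed(geneSeeds[i])
      rg <- runGene(aln, tree, templates, nReplicates = nReplicates,
                    backend = backend, workDir = file.path(geneDir, "work"))
      file.copy(rg$mlcPaths$general, file.path(geneDir, "general.mlc"),
                overwrite = TRUE)
      file.copy(rg$mlcPaths$alternative, file.path(geneDir, "alternative.mlc"),
                overwrite = TRUE)
      writeNewick(tree, file.path(geneDir, "tree.nwk"))
      repLogs[[gid]] <- rg$replicateLog
      lrtRows[[gid]] <- lrtTest(rg$general, rg$alternative)
      if (!is.null(sp) && !is.null(geneTreeDir)) {
        gt <- file.path(geneTreeDir, paste0(gid, ".nwk"))
        if (file.exists(gt)) {
          gtree <- readNewick(gt)
          if (setequal(taxaOf(gtree), taxaOf(aln))) {
            d <- rfDistance(pruneToTaxa(sp, taxaOf(gtree)), gtree)
            rfRows[[gid]] <- data.frame(gene_id = gid, rf_raw = d$rf_raw,
                                        rf_normalized = d$rf_normalized,
                                        stringsAsFactors = FALSE)
          }
        }
      }
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(res)) {
      exclusions <- rbind(exclusions, data.frame(
        gene_id = gid, reason = paste0("analysis_failed: ", res),
        stringsAsFactors = FALSE))
    }
  }

  if (length(lrtRows) == 0L) {
    summary <- data.frame()
  } else {
    summary <- summaryTable(do.call(rbind, lrtRows), alpha = alpha)
    writeTsv(summary, file.path(outDir, "summary.tsv"))
  }
  exclusions <- exclusions[order(exclusions$gene_id), , drop = FALSE]
  rownames(exclusions) <- NULL
  writeTsv(exclusions, file.path(outDir, "exclusions.tsv"))
  repLog <- if (length(repLogs)) do.call(rbind, repLogs) else
    data.frame(gene = character(), model = character(), replicate = integer(),
               start_omega = numeric(), lnl = numeric(), status = character())
  rownames(repLog) <- NULL
  writeTsv(repLog, file.path(outDir, "replicates.tsv"))
  labelsReport <- if (length(labRows)) do.call(rbind, labRows) else NULL
  if (!is.null(labelsReport)) {
    rownames(labelsReport) <- NULL
    writeTsv(labelsReport, file.path(outDir, "labels_report.tsv"))
  }
  rf <- if (length(rfRows)) do.call(rbind, rfRows) else NULL
  if (!is.null(rf)) {
    rownames(rf) <- NULL
    writeTsv(rf, file.path(outDir, "rf_distances.tsv"))
  }
  writeLines(sprintf("seed = %d", as.integer(seed)), file.path(outDir, "run_info.txt"))
  invisible(list(summary = summary, exclusions = exclusions,
                 replicateLog = repLog, rf = rf, labelsReport = labelsReport,
                 outDir = outDir))
}

#' Extract stage: per-clade metric tables across genes
#'
#' Retrieves dN/dS, dN and dS for user-defined branches/clades across genes,
#' including taxon-incomplete ones, under mode A or B (see
#' [extractConfig()]). Input is either an [analyzeGenes()] output directory
#' (the best-fit model of each gene, per its FDR-corrected LRT, is used) or
#' a flat folder of externally produced `<gene>.mlc` files with matching
#' `<gene>.nwk` trees in `treeDir` (each mlc is then used directly).
#'
#' @param input analyze output directory, or a folder of raw mlc files.
#' @param scheme definitions of interest (path or [LabelScheme-class]).
#' @param mode,threshold matching policy, see [extractConfig()].
#' @param treeDir folder of `<gene>.nwk` trees (raw-mlc input only; defaults
#'   to `input`).
#' @param outDir optional output directory for the per-definition TSV
#'   tables and `coverage.tsv`.
#' @return invisibly, list with `tables` and `coverage` (see
#'   [buildExtractTables()]).
#' @export
extractMetrics <- function(input, scheme, mode = "A", threshold = 0.8,
                           treeDir = NULL, outDir = NULL) {
  scheme <- asLabelScheme(scheme)
  cfg <- extractConfig(mode, threshold)
  genes <- list()
  if (file.exists(file.path(input, "summary.tsv"))) {
    summary <- readTsv(file.path(input, "summary.tsv"))
    for (i in seq_len(nrow(summary))) {
      gid <- summary$gene_id[i]
      geneDir <- file.path(input, "genes", gid)
      tree <- readNewick(file.path(geneDir, "tree.nwk"))
      mlc <- file.path(geneDir, paste0(summary$best_model[i], ".mlc"))
      fit <- parseMlc(readLines(mlc, warn = FALSE), tree, geneId = gid,
                      modelTag = summary$best_model[i])
      genes[[gid]] <- list(tree = tree, fit = fit)
    }
  } else {
    if (is.null(treeDir)) treeDir <- input
    mlcs <- sort(list.files(input, pattern = "\\.mlc$", full.names = TRUE))
    if (length(mlcs) == 0L)
      stop("no analyze summary and no .mlc files found in ", input)
    for (f in mlcs) {
      gid <- tools::file_path_sans_ext(basename(f))
      tf <- file.path(treeDir, paste0(gid, ".nwk"))
      if (!file.exists(tf)) stop("no tree file for gene ", gid, ": ", tf)
      tree <- readNewick(tf)
      fit <- parseMlc(readLines(f, warn = FALSE), tree, geneId = gid,
                      modelTag = "best")
      genes[[gid]] <- list(tree = tree, fit = fit)
    }
  }
  res <- buildExtractTables(genes, scheme, cfg)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res$tables))
      writeTsv(res$tables[[nm]], file.path(outDir, paste0(nm, ".tsv")))
    writeTsv(res$coverage, file.path(outDir, "coverage.tsv"))
  }
  invisible(res)
}

#' Gene-tree vs species-tree discordance report
#'
#' For each per-gene tree, prunes the species tree to the gene's taxa and
#' reports raw and normalized Robinson-Foulds distances.
#'
#' @param speciesTree the fixed species tree (path or [Phylogeny-class]).
#' @param geneTreeDir folder of `<gene>.nwk` trees.
#' @param outPath optional TSV output path.
#' @return data.frame `gene_id`, `rf_raw`, `rf_normalized`.
#' @export
rfReport <- function(speciesTree, geneTreeDir, outPath = NULL) {
  sp <- asPhylogeny(speciesTree)
  files <- sort(list.files(geneTreeDir, pattern = "\\.nwk$", full.names = TRUE))
  if (length(files) == 0L) stop("no .nwk gene trees in ", geneTreeDir)
  rows <- lapply(files, function(f) {
    gid <- tools::file_path_sans_ext(basename(f))
    gt <- readNewick(f)
    d <- rfDistance(pruneToTaxa(sp, taxaOf(gt)), gt)
    data.frame(gene_id = gid, rf_raw = d$rf_raw, rf_normalized = d$rf_normalized,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(outPath)) writeTsv(out, outPath)
  out
}

#' Generate a synthetic study dataset
#'
#' Builds a complete, self-consistent input set for the workflow: a random
#' species tree, per-gene codon alignments simulated under the engine's
#' Goldman-Yang model, a foreground clade definition, nested control
#' templates (general: branch model, `model = 2`; alternative: M0,
#' `model = 0`), and per-gene trees. Defaults emulate a small comparative
#' genomics study: 12 species, 10 genes of 300 codons, kappa 2, background
#' omega 0.2 with purifying selection, a minority of genes with an elevated
#' foreground-clade omega, and roughly 70 percent nonubiquitous genes (each
#' gene missing up to 3 random species) — plus, optionally, one gene
#' carrying a premature stop codon to exercise the screen. One gene tree is
#' made deliberately discordant (two tips swapped) for the RF report.
#'
#' @param outDir directory to create the fixture set in.
#' @param nSpecies,nGenes,nCodons dataset dimensions.
#' @param kappa,backgroundOmega,foregroundOmega simulation parameters.
#' @param nForegroundGenes number of genes simulated with the elevated
#'   foreground omega (the rest are null, single-omega genes).
#' @param includeStopGene add a gene with a premature stop codon.
#' @param seed master seed; everything is reproducible from it.
#' @return invisibly, a manifest list: paths of everything written, the
#'   foreground species set and the simulation parameters.
#' @export
simulateFixtures <- function(outDir, nSpecies = 12L, nGenes = 10L,
                             nCodons = 300L, kappa = 2,
                             backgroundOmega = 0.2, foregroundOmega = 0.6,
                             nForegroundGenes = 2L, includeStopGene = TRUE,
                             seed = 1L) {
  stopifnot(nSpecies >= 6L, nGenes >= 1L)
  set.seed(as.integer(seed))
  dir.create(file.path(outDir, "alignments"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "gene_trees"), recursive = TRUE, showWarnings = FALSE)
  spNames <- sprintf("sp%02d", seq_len(nSpecies))
  phy <- ape::rtree(nSpecies, tip.label = spNames,
                    br = function(n) runif(n, 0.05, 0.25))
  spTree <- new("Phylogeny", tree = phy, labels = rep("", nSpecies + phy$Nnode),
                rooted = TRUE)
  # foreground clade: internal node whose size is closest to nSpecies / 3
  desc <- nodeDescendants(phy)
  internal <- (nSpecies + 2L):(nSpecies + phy$Nnode)
  sizes <- lengths(desc[internal])
  ok <- internal[sizes >= 3 & sizes <= nSpecies - 3]
  if (length(ok) == 0L) ok <- internal[which.min(abs(sizes - nSpecies / 3))]
  fgNode <- ok[which.min(abs(lengths(desc[ok]) - nSpecies / 3))]
  fgSpecies <- desc[[fgNode]]
  scheme <- new("LabelScheme", definitions = list(
    cladeDefinition("foreground", fgSpecies, "$1")))
  writeLabelScheme(scheme, file.path(outDir, "labels.tsv"))
  writeNewick(spTree, file.path(outDir, "species_tree.nwk"))

  ctl <- function(model) c(
    "seqfile = SEQFILE", "treefile = TREEFILE", "outfile = OUTFILE",
    "noisy = 0", "verbose = 0", "runmode = 0", "seqtype = 1",
    "CodonFreq = 0", paste("model =", model), "NSsites = 0", "icode = 0",
    "fix_kappa = 0", "kappa = 2", "fix_omega = 0", "omega = OMEGA")
  writeLines(ctl(2), file.path(outDir, "general.ctl"))
  writeLines(ctl(0), file.path(outDir, "alternative.ctl"))

  geneIds <- sprintf("g%02d", seq_len(nGenes))
  manifest <- list(outDir = outDir, speciesTree = file.path(outDir, "species_tree.nwk"),
                   alignmentDir = file.path(outDir, "alignments"),
                   geneTreeDir = file.path(outDir, "gene_trees"),
                   labelScheme = file.path(outDir, "labels.tsv"),
                   generalTemplate = file.path(outDir, "general.ctl"),
                   alternativeTemplate = file.path(outDir, "alternative.ctl"),
                   foregroundSpecies = fgSpecies,
                   params = list(kappa = kappa, backgroundOmega = backgroundOmega,
                                 foregroundOmega = foregroundOmega),
                   genes = geneIds)
  for (i in seq_along(geneIds)) {
    gid <- geneIds[i]
    nMiss <- sample(0:3, 1, prob = c(0.3, 0.3, 0.2, 0.2))
    # keep at least 2 foreground species so the clade survives pruning
    droppable <- setdiff(spNames, fgSpecies[seq_len(min(2L, length(fgSpecies)))])
    taxa <- setdiff(spNames, if (nMiss > 0) sample(droppable, nMiss) else character())
    gtree <- pruneToTaxa(spTree, taxa)
    foreground <- i <= nForegroundGenes
    simTree <- if (foreground) annotateTree(gtree, scheme)$phylogeny else gtree
    omega <- if (foreground)
      c(background = backgroundOmega, "$1" = foregroundOmega) else
      c(background = backgroundOmega)
    aln <- simulateCodonAlignment(simTree, codonModelParams(kappa, omega),
                                  nCodons, geneId = gid)
    writeGeneAlignment(aln, file.path(outDir, "alignments", paste0(gid, ".fas")))
    outTree <- gtree
    if (i == nGenes && length(taxa) >= 4L) {
      # make the last gene tree discordant: swap two non-sister tips
      tp <- outTree@tree
      cand <- utils::combn(seq_along(tp$tip.label), 2L)
      for (j in sample.int(ncol(cand))) {
        pr <- cand[, j]
        m <- ape::getMRCA(tp, tp$tip.label[pr])
        if (length(ape::extract.clade(tp, m)$tip.label) > 2L) {
          tp$tip.label[pr] <- tp$tip.label[rev(pr)]
          break
        }
      }
      outTree <- new("Phylogeny", tree = tp, labels = outTree@labels,
                     rooted = outTree@rooted)
    }
    writeNewick(outTree, file.path(outDir, "gene_trees", paste0(gid, ".nwk")))
  }
  if (includeStopGene) {
    gid <- "g_stop"
    aln <- simulateCodonAlignment(spTree,
                                  codonModelParams(kappa, c(background = backgroundOmega)),
                                  nCodons, geneId = gid)
    seqs <- as.character(aln@sequences)
    substr(seqs[1], 13, 15) <- "TAA"  # premature stop in codon 5
    writeGeneAlignment(codonAlignment(gid, seqs),
                       file.path(outDir, "alignments", paste0(gid, ".fas")))
    manifest$genes <- c(manifest$genes, gid)
  }
  invisible(manifest)
}
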