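ctlLines <- c("seqfile = SEQ", "treefile = TREE", "outfile = OUT",
              "model = 2", "NSsites = 0", "omega = OMEGA")

test_that("control templates render with paths and the replicate's omega", {
  tpl <- readControlTemplate(ctlLines)
  out <- renderControl(tpl, "a.fas", "a.nwk", "a.mlc", 0.7)
  expect_match(out, "omega = 0.7", fixed = TRUE)
  expect_match(out, "seqfile = a.fas", fixed = TRUE)
  expect_match(out, "model = 2", fixed = TRUE)
  expect_error(readControlTemplate(setdiff(ctlLines, "seqfile = SEQ")),
               "missing placeholder.*seqfile")
  a <- strsplit(renderControl(tpl, "x", "y", "z", 0.3), "\n")[[1]]
  b <- strsplit(renderControl(tpl, "x", "y", "z", 1.4), "\n")[[1]]
  expect_identical(a[a != b], "omega = 0.3")  # renders differ only in omega
})

test_that("random omega starts are uniform in [0.05, 2.0], seeded, and distinct", {
  expect_true(all(drawStartOmegas(1, seed = 3) >= 0.05))
  expect_identical(drawStartOmegas(10, seed = 42), drawStartOmegas(10, seed = 42))
  for (s in 1:20) {
    v <- drawStartOmegas(5, seed = s)
    expect_true(all(v >= 0.05 & v <= 2.0))
    expect_length(unique(v), 5L)
  }
})

test_that("mlc parsing extracts lnL/np and keys branch rows by leaf set", {
  tree <- parseNewick("((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
  text <- c("some header",
            "lnL(ntime: 7  np: 9): -1234.567890",
            "",
            " branch           t        N        S    dN/dS        dN        dS",
            "   5..6     0.050000    225.0     75.0  0.200000  0.010000  0.050000",
            "   6..1     0.100000    225.0     75.0  0.200000  0.020000  0.100000",
            "   6..2     0.100000    225.0     75.0  0.200000  0.020000  0.100000",
            "   5..7     0.050000    225.0     75.0  0.300000  0.015000  0.050000",
            "   7..3     0.100000    225.0     75.0  0.300000  0.030000  0.100000",
            "   7..4     0.100000    225.0     75.0  0.300000  0.030000  0.100000")
  fit <- parseMlc(text, tree, geneId = "g", modelTag = "general")
  expect_equal(lnL(fit), -1234.56789)
  expect_equal(nFreeParams(fit), 9L)
  bm <- branchMetrics(fit)
  expect_setequal(bm$key, c("A,B", "A", "B", "C,D", "C", "D"))
  expect_equal(bm$dnds[bm$key == "C"], 0.3)  # leaf edge -> singleton key
  expect_equal(bm$dn[bm$key == "A,B"], 0.01)
  # site-model output: lnL kept, no branch rows
  siteFit <- parseMlc("lnL(ntime: 7  np: 9): -10.5", tree)
  expect_equal(nrow(branchMetrics(siteFit)), 0L)
  expect_equal(lnL(siteFit), -10.5)
  expect_error(parseMlc("no likelihood here", tree), "no lnL line")
  # numbering inconsistent with the supplied tree is refused
  badRow <- c("lnL(ntime: 1  np: 2): -1.0",
              " branch  t  N  S  dN/dS  dN  dS",
              "   6..3  0.1  1  1  0.5  0.1  0.1")
  expect_error(parseMlc(badRow, tree), "inconsistent")
})

test_that("replicate selection takes the max lnL with index tie-break, order-invariant", {
  fits <- list(makeFit(lnl = -100, rep = 1), makeFit(lnl = -99.5, rep = 2),
               makeFit(lnl = -101, rep = 3))
  expect_equal(selectBestReplicate(fits)@replicateIndex, 2L)
  ties <- list(makeFit(lnl = -50, rep = 2), makeFit(lnl = -50, rep = 1))
  expect_equal(selectBestReplicate(ties)@replicateIndex, 1L)
  set.seed(5)
  for (i in 1:10) {
    perm <- sample(fits)
    expect_equal(selectBestReplicate(perm)@lnl, -99.5)
  }
})

test_that("runGene returns per-model best replicates and a complete log", {
  set.seed(91)
  tree <- randomPhylogeny(5, tipNames = c("A", "B", "C", "D", "E"))
  scheme <- new("LabelScheme", definitions = list(
    cladeDefinition("fg", nonRootClade(tree), "#1")))
  tree <- annotateTree(tree, scheme)$phylogeny
  aln <- simulateCodonAlignment(tree, codonModelParams(2, c(background = 0.25)), 60)
  templates <- list(general = readControlTemplate(ctlLines),
                    alternative = readControlTemplate(sub("model = 2", "model = 0", ctlLines)))
  wd <- withr::local_tempdir()
  set.seed(17)
  res <- runGene(aln, tree, templates, nReplicates = 2, workDir = wd)
  expect_s4_class(res$general, "ModelFit")
  expect_equal(res$general@np, 3L)       # kappa + background + "#1"
  expect_equal(res$alternative@np, 2L)   # kappa + single omega
  # nested-model ordering, up to optimizer tolerance
  expect_gte(lnL(res$general) - lnL(res$alternative), -1e-4)
  expect_equal(nrow(res$replicateLog), 4L)
  expect_true(all(res$replicateLog$status == "ok"))
  expect_equal(lnL(res$general), max(res$replicateLog$lnl[
    res$replicateLog$model == "general"]))
  expect_true(file.exists(res$mlcPaths$general))
  # engine refuses site models rather than mis-fitting them
  nsTpl <- readControlTemplate(sub("NSsites = 0", "NSsites = 2", ctlLines))
  expect_error(runGene(aln, tree, list(general = nsTpl, alternative = nsTpl),
                       nReplicates = 1, workDir = withr::local_tempdir()),
               "all 1 replicate")
})
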