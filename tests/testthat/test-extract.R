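toyFitCDE <- function(gene = "g") {
  # fit for tree (A,((C,D),E)) with distinct per-branch metrics
  keys <- c("A", "C", "D", "E", "C,D", "C,D,E")
  makeFit(gene, "general", -10, 3, bm = data.frame(
    key = keys, t = seq(0.1, 0.6, by = 0.1), dnds = seq_along(keys) / 10,
    dn = seq_along(keys) / 100, ds = seq_along(keys) / 50,
    stringsAsFactors = FALSE))
}

test_that("branch species enumeration lists one set per edge", {
  e <- enumerateBranchSpecies(parseNewick("((A,B),(C,D));"))
  expect_length(e, 6L)
  expect_setequal(names(e), c("A", "B", "C", "D", "A,B", "C,D"))
  star <- enumerateBranchSpecies(parseNewick("(A,B,C);"))
  expect_setequal(names(star), c("A", "B", "C"))
  set.seed(67)
  for (i in 1:10) {  # independent subtree-traversal oracle
    p <- randomPhylogeny(sample(4:9, 1))
    phy <- apeTree(p)
    oracle <- sort(vapply(phy$edge[, 2], function(v) leafSetKey(
      phy$tip.label[phangorn::Descendants(phy, v, "tips")[[1]]]), character(1)))
    expect_identical(sort(names(enumerateBranchSpecies(p))), oracle)
  }
})

test_that("definition matching follows the mode A/B rules of the worked examples", {
  defn <- cladeDefinition("x", c("C", "D", "E"), "$1")
  cfgA <- extractConfig("A")
  t1 <- parseNewick("(A,((C,D),E));")
  m1 <- matchDefinition(defn, c("A", "C", "D", "E"), t1, cfgA)
  expect_true(m1$matched)
  expect_identical(m1$matchedKey, "C,D,E")
  # D absent: mode A unmatched
  t2 <- parseNewick("((A,B),(C,E));")
  m2 <- matchDefinition(defn, c("A", "B", "C", "E"), t2, cfgA)
  expect_false(m2$matched)
  expect_identical(m2$reason, "below-threshold")
  # mode B threshold 0.6: |P| = 2 >= ceil(0.6 * 3) = 2 and {C,E} is an edge
  m3 <- matchDefinition(defn, c("A", "B", "C", "E"), t2, extractConfig("B", 0.6))
  expect_true(m3$matched)
  expect_identical(m3$matchedKey, "C,E")
  # present but paraphyletic in the gene tree
  t4 <- parseNewick("((C,A),(D,E));")
  m4 <- matchDefinition(defn, c("A", "C", "D", "E"), t4, cfgA)
  expect_false(m4$matched)
  expect_identical(m4$reason, "not-monophyletic")
})

test_that("an 80% threshold on a 10-species clade requires at least 8 present", {
  sp <- sprintf("s%02d", 1:10)
  defn <- cladeDefinition("big", sp, "$1")
  cfg <- extractConfig("B", 0.8)
  outgroup <- c("o1", "o2")
  for (nPresent in 6:10) {
    present <- sp[seq_len(nPresent)]
    tree <- pruneToTaxa(parseNewick(sprintf("((o1,o2),(%s));",
      paste(sp, collapse = ","))), c(outgroup, present))
    m <- matchDefinition(defn, c(outgroup, present), tree, cfg)
    expect_identical(m$matched, nPresent >= 8L, label = paste("present:", nPresent))
  }
})

test_that("clade-token definitions reduced to one species are unmatched; branch tokens match", {
  tree <- parseNewick("((A,B),(C,X));")
  taxa <- c("A", "B", "C", "X")
  cfg <- extractConfig("B", 1)  # absolute count of one
  mClade <- matchDefinition(cladeDefinition("c", c("C", "D", "E"), "$1"), taxa, tree, cfg)
  expect_false(mClade$matched)
  expect_identical(mClade$reason, "clade-reduced-to-single-species-with-clade-token")
  mBranch <- matchDefinition(cladeDefinition("b", c("C", "D", "E"), "#1"), taxa, tree, cfg)
  expect_true(mBranch$matched)
  expect_identical(mBranch$matchedKey, "C")
})

test_that("matching agrees with brute-force edge enumeration on random inputs", {
  set.seed(71)
  for (i in 1:40) {
    universe <- sprintf("u%02d", 1:10)
    geneTaxa <- sample(universe, sample(4:10, 1))
    geneTree <- randomPhylogeny(length(geneTaxa), tipNames = geneTaxa)
    defn <- cladeDefinition("d", sample(universe, sample(1:8, 1)),
                            sample(c("#1", "$1"), 1))
    for (cfg in list(extractConfig("A"), extractConfig("B", runif(1, 0.3, 0.99)),
                     extractConfig("B", sample(1:6, 1)))) {
      expect_identical(matchDefinition(defn, geneTaxa, geneTree, cfg)$matched,
                       bruteForceMatch(defn, geneTaxa, geneTree, cfg),
                       label = sprintf("case %d mode %s", i, cfg@mode))
    }
  }
})

test_that("lowering the mode-B threshold never unmatches a matched gene", {
  set.seed(73)
  for (i in 1:20) {
    universe <- sprintf("u%02d", 1:9)
    geneTaxa <- sample(universe, sample(4:9, 1))
    geneTree <- randomPhylogeny(length(geneTaxa), tipNames = geneTaxa)
    defn <- cladeDefinition("d", sample(universe, sample(2:7, 1)), "#1")
    thresholds <- sort(runif(4, 0.2, 1))
    matched <- vapply(thresholds, function(th)
      matchDefinition(defn, geneTaxa, geneTree, extractConfig("B", th))$matched,
      logical(1))
    # matched is monotone nonincreasing as the threshold rises
    expect_true(all(diff(matched) <= 0))
  }
})

test_that("mode A equals mode B at full required presence", {
  set.seed(79)
  for (i in 1:20) {
    universe <- sprintf("u%02d", 1:8)
    geneTaxa <- sample(universe, sample(4:8, 1))
    geneTree <- randomPhylogeny(length(geneTaxa), tipNames = geneTaxa)
    defn <- cladeDefinition("d", sample(universe, sample(2:6, 1)), "$1")
    full <- extractConfig("B", length(defn@species))  # absolute = |definition|
    expect_identical(matchDefinition(defn, geneTaxa, geneTree, extractConfig("A"))$matched,
                     matchDefinition(defn, geneTaxa, geneTree, full)$matched)
  }
})

test_that("pruning a monophyletic definition keeps it monophyletic in the gene tree", {
  set.seed(83)
  for (i in 1:15) {
    sp <- randomPhylogeny(sample(7:11, 1))
    tips <- taxaOf(sp)
    defSp <- nodeDescendantsOf(sp, mrcaNode(sp, sample(tips, 2)))
    if (length(defSp) > length(tips) - 2) next
    keep <- sort(sample(tips, sample(4:(length(tips) - 1), 1)))
    gt <- pruneToTaxa(sp, keep)
    present <- intersect(defSp, keep)
    if (length(present) < 2) next
    node <- mrcaNode(gt, present)
    expect_setequal(nodeDescendantsOf(gt, node), present)
  }
})

test_that("metric retrieval distinguishes branch and clade semantics", {
  fit <- toyFitCDE()
  cfg <- extractConfig("A")
  tree <- parseNewick("(A,((C,D),E));")
  mB <- matchDefinition(cladeDefinition("b", c("C", "D"), "#1"),
                        taxaOf(tree), tree, cfg)
  rowsB <- retrieveMetrics(mB, fit, cladeDefinition("b", c("C", "D"), "#1"))
  expect_equal(nrow(rowsB), 1L)
  expect_identical(rowsB$scope, "stem")
  expect_identical(rowsB$branch, "C,D")
  defC <- cladeDefinition("c", c("C", "D", "E"), "$1")
  mC <- matchDefinition(defC, taxaOf(tree), tree, cfg)
  rowsC <- retrieveMetrics(mC, fit, defC)
  expect_setequal(rowsC$branch[rowsC$scope != "derived-mean"],
                  c("C,D,E", "C,D", "C", "D", "E"))
  agg <- rowsC[rowsC$scope == "derived-mean", ]
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$dnds, mean(rowsC$dnds[rowsC$scope != "derived-mean"]))
  # a fit with no branch table yields a metrics-missing signal, not a row
  expect_null(retrieveMetrics(mC, makeFit("g", "general", -10, 3), defC))
})

test_that("table assembly reports unmatched genes and fails on empty definitions", {
  tree1 <- parseNewick("(A,((C,D),E));")
  tree2 <- pruneToTaxa(tree1, c("A", "C", "E"))
  tree3 <- pruneToTaxa(tree1, c("A", "D", "E"))
  genes <- list(g1 = list(tree = tree1, fit = toyFitCDE("g1")),
                g2 = list(tree = tree2, fit = makeFit("g2")),
                g3 = list(tree = tree3, fit = makeFit("g3")))
  scheme <- new("LabelScheme", definitions = list(
    cladeDefinition("cde", c("C", "D", "E"), "$1")))
  res <- buildExtractTables(genes, scheme, extractConfig("A"))
  expect_equal(sum(res$coverage$status == "matched"), 1L)
  expect_equal(sum(res$coverage$status == "unmatched" &
                     res$coverage$reason == "below-threshold"), 2L)
  expect_true(all(res$tables$cde$gene_id == "g1"))
  expect_error(buildExtractTables(genes, new("LabelScheme", definitions = list()),
                                  extractConfig("A")), "no branch/clade definitions")
})
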