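test_that("newick parsing preserves structure, lengths and PAML labels", {
  p <- parseNewick("((A,B),(C,D));")
  expect_equal(sort(taxaOf(p)), c("A", "B", "C", "D"))
  expect_equal(apeTree(p)$Nnode, 3L)  # two internal nodes + root
  p2 <- parseNewick("((A:0.1,B:0.2):0.05,C:0.3);")
  expect_equal(sort(apeTree(p2)$edge.length), c(0.05, 0.1, 0.2, 0.3))
  p3 <- parseNewick("((A,B)#1,(C,D));")
  nt <- length(apeTree(p3)$tip.label)
  labNode <- which(nzchar(pamlLabels(p3)))
  expect_equal(pamlLabels(p3)[labNode], "#1")
  expect_setequal(nodeDescendantsOf(p3, labNode), c("A", "B"))
})

test_that("malformed newick fails with position info; duplicate leaves are fatal", {
  expect_error(parseNewick("((A,B),(C,D);"), "unbalanced")
  expect_error(parseNewick("(A,B)),C;"), "unbalanced.*character [0-9]+")
  expect_error(parseNewick("((A,B),(A,C));"), "duplicate leaf names: A")
})

test_that("parse -> write -> parse is topology- and label-stable", {
  txts <- c("((A:0.1,B:0.2) #1:0.05,(C:0.1,D:0.1) $2:0.3);",
            "(A #1:0.1,B:0.2,(C:0.1,D:0.1,E:0.2) $1:0.3);",
            "((A,B),(C,D));")
  for (txt in txts) {
    p1 <- parseNewick(txt)
    p2 <- parseNewick(writeNewick(p1))
    expect_identical(writeNewick(p1), writeNewick(p2))
    expect_equal(rfDistance(p1, p2)$rf_raw, 0L)
    expect_identical(sort(pamlLabels(p1)[nzchar(pamlLabels(p1))]),
                     sort(pamlLabels(p2)[nzchar(pamlLabels(p2))]))
  }
})

test_that("pruning keeps topology, sums suppressed branch lengths, errors as specified", {
  t1 <- pruneToTaxa(parseNewick("((A,B),(C,D));"), c("A", "C", "D"))
  expect_equal(writeNewick(t1), writeNewick(parseNewick("(A,(C,D));")))
  full <- parseNewick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_identical(writeNewick(pruneToTaxa(full, taxaOf(full))), writeNewick(full))
  t2 <- pruneToTaxa(parseNewick("((A:1,B:1):1,C:2);"), c("A", "C"))
  # A's path collapses 1 + 1 into a single branch of length 2
  expect_equal(sort(apeTree(t2)$edge.length), c(2, 2))
  expect_error(pruneToTaxa(full, "A"), "fewer than 2")
  expect_error(pruneToTaxa(full, c("A", "Z")), "not in tree: Z")
})

test_that("nested prunes collapse: prune(prune(T,S1),S2) = prune(T,S2) for S2 in S1", {
  set.seed(11)
  for (i in 1:15) {
    p <- randomPhylogeny(sample(6:12, 1))
    tips <- taxaOf(p)
    s1 <- sample(tips, sample(4:(length(tips) - 1), 1))
    s2 <- sample(s1, sample(2:(length(s1) - 1), 1))
    expect_identical(writeNewick(pruneToTaxa(pruneToTaxa(p, s1), s2)),
                     writeNewick(pruneToTaxa(p, s2)))
  }
})

test_that("bipartitions enumerate exactly the nontrivial internal edges", {
  expect_identical(bipartitions(parseNewick("((A,B),(C,D));")), "C,D")
  expect_identical(bipartitions(parseNewick("(A,B,C,D,E);")), character())
  expect_length(bipartitions(parseNewick("((((A,B),C),D),E);")), 2L)
})

test_that("RF distance matches examples and is a proper normalized symmetric distance", {
  a <- parseNewick("((A,B),(C,D));")
  expect_equal(rfDistance(a, a), list(rf_raw = 0L, rf_normalized = 0))
  b <- parseNewick("((A,C),(B,D));")
  expect_equal(rfDistance(a, b), list(rf_raw = 2L, rf_normalized = 1))
  expect_equal(rfDistance(b, a), rfDistance(a, b))
  # two stars: distance defined as 0
  s <- parseNewick("(A,B,C,D);")
  expect_equal(rfDistance(s, s)$rf_normalized, 0)
  expect_error(rfDistance(a, parseNewick("((A,B),(C,E));")), "leaf sets differ")
})

test_that("raw RF on random binary pairs equals the phangorn split-set oracle", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(5:10, 1)
    p1 <- randomPhylogeny(n)
    p2 <- randomPhylogeny(n)
    mine <- rfDistance(p1, p2)
    oracle <- phangorn::RF.dist(apeTree(p1), apeTree(p2))
    expect_equal(mine$rf_raw, as.integer(oracle), label = paste("pair", i))
    expect_gte(mine$rf_normalized, 0)
    expect_lte(mine$rf_normalized, 1)
  }
})
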