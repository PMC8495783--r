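test_that("the GY94 generator has the required structure", {
  set.seed(3)
  f <- runif(61); f <- f / sum(f)
  Q <- buildRateMatrix(kappa = 3, omega = 0.4, codonFreqs = f)
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  # no direct exchange between codons differing at >1 position
  s <- phyloOmega:::codonSetup()
  multi <- which(!s$one & row(Q) != col(Q))
  expect_true(all(Q[multi] == 0))
  # detailed balance pi_i q_ij = pi_j q_ji over all pairs
  expect_equal(Q * f, t(Q * f), tolerance = 1e-12)
  # unit expected rate at equilibrium
  expect_equal(-sum(f * diag(Q)), 1, tolerance = 1e-12)
})

test_that("zero-length branches give lnL = sum of log codon frequencies", {
  tr <- parseNewick("(A:0,B:0);")
  aln <- codonAlignment("g", c(A = "ATGAAATGC", B = "ATGAAATGC"))
  ll <- codonLogLikelihood(aln, tr, codonModelParams(2, c(background = 0.5)))
  expect_equal(ll, 3 * log(1 / 61), tolerance = 1e-10)
})

test_that("pruning likelihood equals exhaustive enumeration over internal states", {
  # independent oracle: Matrix::expm for transition matrices, brute-force
  # sum over both internal-node codon assignments of a 3-taxon tree
  tr <- parseNewick("((A:0.08,B:0.22):0.1,C:0.15);")
  set.seed(41)
  aln <- simulateCodonAlignment(tr, codonModelParams(2.5, c(background = 0.3)), 3)
  kappa <- 1.7; omega <- 0.6
  ll <- codonLogLikelihood(aln, tr, codonModelParams(kappa, c(background = omega)))
  s <- phyloOmega:::codonSetup()
  Q <- buildRateMatrix(kappa, omega)
  P <- function(t) as.matrix(Matrix::expm(Q * t))
  Pa <- P(0.08); Pb <- P(0.22); Pc <- P(0.15); Pi <- P(0.1)
  x <- lapply(taxaOf(aln), function(sp) {
    seq <- as.character(aln@sequences[[sp]])
    match(substring(seq, c(1, 4, 7), c(3, 6, 9)), s$codons)
  })
  names(x) <- taxaOf(aln)
  pi0 <- rep(1 / 61, 61)
  oracle <- 0
  for (site in 1:3) {
    lik <- 0
    for (r in 1:61) for (m in 1:61) {
      lik <- lik + pi0[r] * Pi[r, m] * Pa[m, x$A[site]] * Pb[m, x$B[site]] *
        Pc[r, x$C[site]]
    }
    oracle <- oracle + log(lik)
  }
  expect_equal(ll, oracle, tolerance = 1e-8)
})

test_that("the likelihood is invariant under re-rooting (reversibility)", {
  set.seed(47)
  tr <- randomPhylogeny(6)
  aln <- simulateCodonAlignment(tr, codonModelParams(2, c(background = 0.4)), 40)
  par <- codonModelParams(1.8, c(background = 0.35))
  ll1 <- codonLogLikelihood(aln, tr, par)
  un <- ape::unroot(apeTree(tr))
  tr2 <- new("Phylogeny", tree = un,
             labels = rep("", length(un$tip.label) + un$Nnode), rooted = FALSE)
  expect_equal(codonLogLikelihood(aln, tr2, par), ll1, tolerance = 1e-8)
  re <- ape::root(un, outgroup = taxaOf(tr)[1], resolve.root = TRUE)
  tr3 <- new("Phylogeny", tree = re,
             labels = rep("", length(re$tip.label) + re$Nnode), rooted = TRUE)
  expect_equal(codonLogLikelihood(aln, tr3, par), ll1, tolerance = 1e-8)
})

test_that("labeled branches use their own omega class in the likelihood", {
  tr <- parseNewick("((A:0.1,B:0.1) #1:0.1,(C:0.1,D:0.1):0.1);")
  set.seed(53)
  aln <- simulateCodonAlignment(tr, codonModelParams(2, c(background = 0.2, "#1" = 2)), 50)
  par2 <- codonModelParams(2, c(background = 0.2, "#1" = 2))
  parFlat <- codonModelParams(2, c(background = 0.2, "#1" = 0.2))
  # with equal class omegas the labeled tree reduces to M0
  trPlain <- parseNewick("((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  expect_equal(codonLogLikelihood(aln, tr, parFlat),
               codonLogLikelihood(aln, trPlain, codonModelParams(2, c(background = 0.2))),
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(codonLogLikelihood(aln, tr, par2),
                                codonLogLikelihood(aln, tr, parFlat))))
})

test_that("adding a free omega class never decreases the maximized lnL", {
  set.seed(59)
  for (i in 1:3) {
    tr <- randomPhylogeny(5)
    # pick a clade below the root so the "#" stem branch actually exists
    scheme <- new("LabelScheme", definitions = list(
      cladeDefinition("fg", nonRootClade(tr), "#1")))
    trLab <- annotateTree(tr, scheme)$phylogeny
    aln <- simulateCodonAlignment(trLab, codonModelParams(2, c(background = 0.3)), 80)
    m0 <- fitCodonModel(aln, trLab, "M0")
    br <- fitCodonModel(aln, trLab, "branch")
    expect_gte(lnL(br) - lnL(m0), -1e-4)
    expect_equal(nFreeParams(m0), 2L)
    expect_equal(nFreeParams(br), 3L)
  }
})

test_that("the simulator is seed-reproducible, respects n = 0, and hits equilibrium", {
  tr <- randomPhylogeny(4)
  par <- codonModelParams(2, c(background = 0.5))
  a1 <- simulateCodonAlignment(tr, par, 30, seed = 77)
  a2 <- simulateCodonAlignment(tr, par, 30, seed = 77)
  expect_identical(as.character(a1@sequences), as.character(a2@sequences))
  empty <- simulateCodonAlignment(tr, par, 0, seed = 1)
  expect_equal(nCodons(empty), 0L)
  expect_equal(length(empty@sequences), 4L)
  # long branches: codon usage converges to the (uniform) equilibrium
  star <- parseNewick("(A:40,B:40,C:40,D:40);")
  big <- simulateCodonAlignment(star, par, 2000, seed = 99)
  s <- phyloOmega:::codonSetup()
  counts <- table(factor(match(substring(
    paste(as.character(big@sequences), collapse = ""),
    seq(1, 8 * 3 * 2000, 3), seq(3, 8 * 3 * 2000, 3)), s$codons), levels = 1:61))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("emulated mlc output round-trips through the parser", {
  set.seed(61)
  tr <- randomPhylogeny(6)
  scheme <- new("LabelScheme", definitions = list(
    cladeDefinition("fg", sample(taxaOf(tr), 3), "$1")))
  trLab <- annotateTree(tr, scheme)$phylogeny
  fit <- new("EngineFit", kappa = 2.3, omega = c(background = 0.21, "$1" = 1.4),
             codonFreqs = rep(1 / 61, 61), lnl = -4321.123456, np = 3L,
             converged = TRUE)
  mlc <- emulateCodemlOutput(fit, trLab, "gX", nCodons = 200)
  parsed <- parseMlc(mlc, trLab, geneId = "gX")
  expect_equal(lnL(parsed), fit@lnl, tolerance = 1e-6)
  expect_identical(nFreeParams(parsed), 3L)
  bm <- branchMetrics(parsed)
  expect_equal(nrow(bm), nrow(apeTree(trLab)$edge))  # one row per edge
  # per-branch dN/dS equals the omega of that branch's class
  ec <- phyloOmega:::edgeClassTokens(trLab)
  desc <- phyloOmega:::nodeDescendants(ec$phy)
  for (k in seq_len(nrow(ec$edge))) {
    key <- leafSetKey(desc[[ec$edge[k, 2]]])
    expect_equal(bm$dnds[bm$key == key], unname(fit@omega[[ec$classes[k]]]),
                 tolerance = 1e-6)
  }
})
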