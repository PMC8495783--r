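---
title: "Selection-regime analysis with nonubiquitous genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-regime analysis with nonubiquitous genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloOmega)
```

## The problem

Comparative genomics datasets typically contain many more *nonubiquitous*
single-copy orthologs — genes missing from one or more of the sampled
species — than *ubiquitous* ones found in every species. Selection analyses
based on codon models (dN/dS, also written $\omega$) are usually restricted
to the ubiquitous fraction because the standard tooling assumes one fixed
taxon set. phyloOmega automates the two steps needed to lift that
restriction:

* **analyze** — for each gene: screen the in-frame alignment for stop
  codons, prune the species tree to the species actually present, re-derive
  any branch/clade rate labels on the pruned tree, fit a *general* and a
  nested *alternative* codon model (several replicates each, from random
  $\omega$ starting values), and compare them by a likelihood-ratio test
  with false-discovery-rate correction across genes.
* **extract** — for each user-defined branch or clade of interest: decide,
  gene by gene, whether an *equivalent* branch/clade still exists in the
  (possibly taxon-incomplete) gene tree, and if so pull its dN/dS, dN and
  dS out of the gene's best-fit model output.

A note on naming: following the workflow convention this package adopts, the
**alternative** model is the *restricted* one, nested within the **general**
model. This inverts the usual statistical usage; the LRT asks whether the
general model's extra parameters are justified, and the restricted model is
kept unless the FDR-adjusted test rejects it.

## The codon model

The built-in engine implements the Goldman–Yang codon substitution process
on the 61 sense codons of the standard genetic code. The instantaneous rate
from codon $i$ to $j$ is

$$
q_{ij} = \begin{cases}
0 & \text{more than one position differs} \\
\pi_j & \text{synonymous transversion} \\
\kappa \pi_j & \text{synonymous transition} \\
\omega \pi_j & \text{nonsynonymous transversion} \\
\omega \kappa \pi_j & \text{nonsynonymous transition,}
\end{cases}
$$

scaled so the expected substitution rate at equilibrium is one (branch
lengths are expected substitutions per codon). Under the M0 model a single
$\omega$ applies everywhere; under the branch model each PAML label token
(`#k` = one branch, `$k` = a whole clade, stem included) defines its own
$\omega$ class, with unlabeled branches forming the background class.
Likelihoods are computed by Felsenstein pruning over unique site patterns;
transition matrices $e^{Qt}$ come from an eigendecomposition of the
reversible generator in the $\sqrt{\pi}$-symmetrized basis, which is stable
and cheap at 61 states. Codons containing gaps, `N`, or stops contribute an
all-ones conditional vector (missing data).

The engine is deliberately minimal — it exists so the whole pipeline runs
and is testable end to end without an external binary, and so the package
can simulate data and emulate CodeML outputs with known truth:

* codon frequencies are equal (1/61) by default; no F3x4 estimation;
* only the standard genetic code is supported in the likelihood (screening
  supports any NCBI table);
* branch lengths are taken from the input tree and **not** re-optimized, so
  a fit has $np = 1 + \#\text{classes}$ free parameters ($\kappa$ plus one
  $\omega$ per class);
* site-class (NSsites) and branch-site likelihoods are out of scope; the
  mlc parser and the LRT layer still handle any nested pair at the lnL/np
  level, so such fits can be consumed from external CodeML outputs.

Optimization is bounded L-BFGS-B on log-transformed parameters with
$\kappa \in [0.01, 50]$ and $\omega \in [10^{-4}, 20]$, relative likelihood
tolerance around $10^{-9}$, and one fallback restart from
$(\kappa, \omega) = (2, 0.5)$ if the requested start is degenerate.

## Tunable parameters and defaults

| parameter | default | meaning and rationale |
|---|---|---|
| `nReplicates` | 2 | fits per model per gene; each replicate starts from a fresh random $\omega$ |
| random $\omega$ start range | $[0.05, 2.0]$ | uniform; bounded away from the $\omega = 0$ boundary |
| `minTaxa` | 4 | below four taxa there is no informative internal branch |
| `alpha` | 0.05 | FDR level for best-model selection (strict inequality; ties keep the restricted model) |
| genetic code | NCBI table 1 | used for stop-codon screening; overridable per run |
| extract `mode` | A | require the full clade present; mode B tolerates missing species inside it |
| extract `threshold` | 0.8 | mode B: values `< 1` are proportions (`ceiling(threshold * clade size)` — "at least" semantics), values `>= 1` absolute counts; the boundary value 1 is an absolute count of one, full presence is written as mode A |

Replicate selection takes the maximum log-likelihood, with exact ties broken
by the lowest replicate index, so results are invariant under replicate
reordering. A negative LRT statistic (the restricted model apparently ahead,
a local-optimum symptom) is clamped to zero and flagged rather than rerun:
replicates already mitigate local optima, and silent reruns would harm
reproducibility.

## Matching branches and clades across incomplete gene trees

Every branch is identified by its descendant leaf set, never by node
numbers, which differ between pruned trees; CodeML's numbering (leaves in
sequence-file order, internal nodes parent-first) is reproduced only
transiently while parsing an mlc file, and the parser refuses output whose
branch rows are inconsistent with the supplied tree.

For a definition with species set $D$ and a gene with taxa $G$, let
$P = D \cap G$. The definition matches iff $P$ meets the presence
requirement (mode A: $P = D$; mode B: $|P| \geq$ threshold) **and** $P$ is
the exact descendant leaf set of some edge of the gene tree. The exact-edge
requirement is a deliberate strictness: for gene trees discordant with the
species tree the reduced set may be non-monophyletic, and attributing
metrics to a branch that does not exist would be worse than reporting
`not-monophyletic`. A clade (`$`) definition reduced to a single present
species is unmatched — no clade remains — while a branch (`#`) definition
matches the terminal branch. No constraint is placed on species missing
*outside* the clade of interest.

For a matched clade definition, extract returns the stem row, every branch
row inside the clade, and an unweighted-mean row explicitly marked
`derived-mean`; the aggregate is a convenience, never a substitute for the
per-branch rows.

Labels are re-derived on each pruned tree from the surviving species of each
definition, so annotation commutes with pruning whenever the defined species
survive. Definitions whose present species are not monophyletic in a tree
are still labeled at the MRCA but loudly flagged: flagging preserves user
control without silently changing CodeML's semantics. Both whole-clade
labels and singleton (terminal-branch) labels are supported.

## Gene tree / species tree discordance

In fixed-species-tree mode with per-gene trees available, the workflow
reports the Robinson–Foulds distance between each gene tree and the species
tree pruned to the gene's taxa. RF is computed on unrooted nontrivial split
sets; the normalization divides the raw symmetric difference by the total
number of nontrivial splits in the two trees, which extends gracefully to
multifurcating trees (two star trees are at distance 0 by convention). This
normalization choice is the package's own — several exist in the literature
— and for a pair of binary trees it reduces to the usual $2(n-3)$
denominator.

## The synthetic-data generator

`simulateFixtures()` builds a full study input set: a random species tree
(12 species by default, branch lengths uniform on $[0.05, 0.25]$
substitutions/codon — shallow enough to avoid dS saturation, deep enough to
be informative), 10 genes of 300 codons at $\kappa = 2$, background
$\omega = 0.2$ (typical purifying selection), a foreground clade of roughly
a third of the species with $\omega = 0.6$ in a minority of genes (a clear
but not caricatural relaxation signal), and per-gene taxon sets missing up
to three species each so that roughly 70% of genes are nonubiquitous,
echoing the composition of real comparative datasets. One gene carries a
premature stop codon to exercise the screen, and one gene tree has two
non-sister tips swapped to exercise the discordance report.

What the generator does **not** emulate — and therefore what passing tests
cannot show about real data: alignment error, within-gene rate
heterogeneity across sites, codon-usage bias (frequencies are uniform),
saturation on deep branches, paralogy/orthology confusion, and biased
(non-random) patterns of gene absence. The generator's role is to provide
inputs with known truth for correctness and calibration checks, not to
mimic any particular empirical dataset.

## Numerical and design choices

* **Pattern likelihoods** are rescaled per node (column sums) to avoid
  underflow; eigendecomposition is performed once per $(\kappa, \omega)$
  class per evaluation.
* **Pruning** sums the branch lengths of suppressed unifurcations, so path
  lengths — and thus likelihoods computed on pruned trees — are preserved.
* **Degenerate inputs**: an empty alignment directory is fatal; a malformed
  gene is excluded with a reason, never fatal to the batch; a gene whose
  labels all vanish after pruning makes the branch model collapse onto M0
  and the gene is logged as failed (the nested pair is no longer a pair).
* **Determinism**: one master seed; per-gene seeds are derived from it by a
  seeded draw, so batch results are identical regardless of gene scheduling
  order, and outputs are sorted by gene id.
* **FDR** is Benjamini–Hochberg, applied across all genes' LRT p-values.
* The chi-square degrees of freedom come from the np difference reported in
  the fits, not from model structure, so arbitrary user-supplied nested
  pairs are supported. Boundary-corrected (mixture) nulls for branch-site
  tests are not implemented; the raw chi-square is used.

## Study conditions used by the test suite

The package's checks run at sizes chosen to be statistically meaningful on
a single CPU: the likelihood is verified against exhaustive enumeration on
3-taxon, 3-codon instances (tolerance $10^{-8}$); $\omega$ recovery uses 50
simulated alignments of 500 codons on an 8-taxon tree at $\omega = 0.2$,
$\kappa = 2$ (the mean estimate must sit within two standard errors of the
truth); LRT calibration uses 200 null simulations of 150 codons on a
6-taxon tree, where the rejection rate at $\alpha = 0.05$ must fall inside
the binomial envelope $[0.02, 0.09]$; and clade matching is compared with a
brute-force edge-enumeration oracle across hundreds of random trees and
thousands of species subsets.

## Known limitations

The engine is a testing and small-study backend, not a CodeML replacement:
for publication-grade analyses of site or branch-site models, or with
estimated codon frequencies, run the external binary (`backend = "codeml"`)
and let the package handle control files, replicates, parsing, LRT, FDR and
extraction. RF normalization and the extract-stage monophyly strictness are
documented package choices; both are exposed so downstream users can audit
which genes were excluded and why.
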