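Package: phyloOmega
Title: Batch Selection-Regime Analysis of Coding Genes with Branch and
    Clade dN/dS Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A two-stage workflow for phylogeny-based selection analyses of
    protein-coding genes, designed to integrate nonubiquitous genes (single
    copy orthologs missing from some species). The "analyze" stage screens
    codon alignments for stop codons, prunes the species tree to each gene's
    taxon set, places PAML-style branch (#) and clade ($) labels, runs paired
    nested codon-model fits with replicate random omega starts (through an
    external CodeML binary or the built-in Goldman-Yang engine), and compares
    them by likelihood-ratio tests with false-discovery-rate correction. The
    "extract" stage identifies equivalent branches and clades across
    taxon-incomplete gene trees, applies missing-species thresholds, and
    assembles per-clade tables of dN/dS, dN and dS under each gene's best-fit
    model. Includes a codon-alignment simulator, a CodeML output emulator,
    and normalized Robinson-Foulds reporting of gene-tree versus species-tree
    discordance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
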