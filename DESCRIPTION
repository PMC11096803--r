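Package: picobirnatax
Title: Consensus Genus Delimitation, Virus-Host Cophylogeny, and
    Ribosome-Binding-Site Scanning for Segmented RNA Viruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for three linked questions about poorly classified RNA
    virus families such as the Picobirnaviridae: delimiting candidate genera
    as clades that stay well supported across an ensemble of phylogenies
    (seed detection by stem length and SH-aLRT support, per-tree membership
    assessment, core-sequence consensus); quantifying virus-host phylogenetic
    congruence with the normalized Penny-Hendy (nPH85) bipartition distance
    and an undated duplication-transfer-loss maximum-parsimony reconciliation
    that counts and uniformly samples optimal reconciliations to estimate
    event likelihoods; and scanning the 24-nt regions upstream of annotated
    open reading frames for prokaryotic Shine-Dalgarno ribosome-binding-site
    motifs, with exact longest-motif class frequencies. Seeded simulators
    generate paired virus-host histories, clustered tree ensembles, and
    motif-planted genome segments with known ground truth, and a config-driven
    pipeline orchestrates all three analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
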