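---
title: "Methods: consensus genus delimitation, cophylogeny, and RBS scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus genus delimitation, cophylogeny, and RBS scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picobirnatax)
```

This vignette documents the models and procedures the package implements,
the parameters that matter and their defaults, the design choices made
where more than one reading was defensible, and what the simulators do and
do not emulate. The motivating application is the *Picobirnaviridae*, a
family of bisegmented dsRNA viruses sampled overwhelmingly from animal
faeces whose true hosts are contested; all three analyses generalize to
any virus group with an ensemble of trees, a host annotation, and
annotated genome segments.

## Tree substrate

Trees are `ape::phylo` objects. Internal-node support values (SH-aLRT
percentages as emitted by IQ-TREE) travel in `node.label`; `parse_newick()`
also accepts the bracket-comment dialect `")[85]:0.1"` and validates
supports into [0, 100], tip-label uniqueness and non-negative branch
lengths. Polytomies are first-class throughout: hand-built host cladograms
are typically polytomous, and no operation silently resolves one (the DTL
reconciliation, which needs binary trees, resolves host polytomies with a
*seeded, reported* resolution, and refuses polytomous virus trees).

Bipartitions are canonicalized as the smaller side of each non-trivial
split (ties: the side holding the lexicographically smallest tip), which
makes split sets independent of rooting; this is checked property-style
against an edge-deletion flood-fill oracle. `midpoint_root()` places the
root halfway along the longest tip-to-tip path, breaking ties among
equally long paths by the lexicographically smallest tip pair so rooting
is deterministic; `phangorn::midpoint` is used in tests as an independent
check of the root position.

## Consensus genus delimitation

The published practice this formalizes is: pick well-supported, long-stem
clusters on a midpoint-rooted reference tree, annotate them across an
ensemble of trees built with different outgroups and rootings, and keep as
*core* sequences only those that cluster within their draft genus with
≥ 80 % support in every tree. Two steps were open to interpretation and
are made explicit here:

- **Seed detection** (`detect_seeds()`): the original clusters were picked
  partly by eye. The package's explicit rule is: MRCA support
  ≥ `min_support` (default 80), stem branch ≥ `min_stem_factor` (default
  2) times the median internal branch length, size ≥ `min_seed_size`
  (default 5), keeping only maximal qualifying clades. User-supplied
  seeds bypass detection entirely, which is the faithful route when
  reproducing a published delimitation.
- **Membership in one tree** (`assess_membership()`): "clustering within
  the draft genus with ≥ 80 % support" is operationalized as: among
  internal nodes with support ≥ `min_support` whose tip sets are at least
  `purity` (default 0.90) seed members, take the node holding the most
  seed members (ties: higher purity, then smaller clade, then smallest
  tip set). The strict alternative — requiring perfect monophyly of the
  whole seed — would unclassify an entire genus whenever a single rogue
  taxon moved, which contradicts the intended behaviour of retaining the
  vast majority of sequences; the purity parameter tolerates a small
  number of interlopers without dissolving the genus.

`classify_ensemble()` performs a single exclusion pass (no iteration, as a
single pass is what the published procedure describes): a tip is assigned
iff it is inside its seed's representative clade in every tree. By default
all ensemble trees must share the tip set; `require_all_tips = FALSE`
relaxes this to "consistent in every tree where present" for
outgroup-restricted ensembles. Seeds are evaluated independently — whether
excluded sequences should first be removed before checking other seeds is
unstated in the source procedure, and independent evaluation is
order-free and deterministic.

## Virus–host congruence

### nPH85

`nph85()` computes the normalized Penny–Hendy distance
`|B_v Δ B_h| / (|B_v| + |B_h|)` over non-trivial bipartitions of the
unrooted trees, 0 on identical topologies, 1 when no splits are shared.
Virus tip sets are much larger than host cladogram tip sets (many viruses
per host), and the published pipelines do not document how the leaf sets
were bridged, so the package exposes two explicit modes and records which
was used:

- `"expanded-host-tree"` (default): each host tip becomes a polytomy of
  its mapped virus tips; unmapped hosts are pruned. One deterministic
  comparison.
- `"resample-one-per-host"`: repeatedly draw one virus per host (seeded),
  restrict both trees, compare, and report the mean over draws.

The expanded mode treats the host polytomies as hard, which biases the
distance upward when many viruses share a host (the virus tree resolves
where the host tree cannot); the resampling mode avoids that at the cost
of stochasticity. Degenerate case: when neither restricted tree has a
non-trivial split the distance is defined as 0.

### DTL reconciliation

`reconcile_mpr()` implements an undated
duplication–transfer–loss dynamic program. Each internal virus node is
mapped to a host node and labelled co-divergence (children split across
the host node's two child subtrees), duplication (both children at or
below the same host node) or transfer (one child stays, the other lands
on any host edge not ancestrally related to the donor); losses are
charged per host edge crossed while a lineage is passed down. The host
tree is an undated cladogram, so transfers are constrained only by
non-ancestrality — no further time consistency is imposed or imposable.
Event costs default to (0, 1, 1, 1) for co-divergence, transfer,
duplication, loss; "extinction" in the output is the loss event under its
other common name.

Alongside the minimum cost the DP counts the *exact* number of distinct
optimal reconciliations, where a reconciliation is the full assignment of
host positions and event labels (two reconciliations differing only in
label at identical positions are distinct). Counts are held in R doubles
and therefore exact up to 2^53 — far beyond the instance sizes exercised
here, but a documented limitation for enormous MPR sets.
`event_likelihoods()` draws reconciliations uniformly from the MPR set by
stochastic backtracking weighted by the DP's solution counts (the
published analyses report "event likelihoods ... with 100 replicates"
without defining the replicate mechanism; uniform MPR sampling is the
defensible reading and is what the 100-sample default emulates). Event
proportions use all events including losses as the denominator, matching
the "proportion of all possible events" convention.

Correctness is established against an independent oracle that enumerates
every placement of internal virus nodes over host nodes and scores label
choices per node: on hundreds of random instances with ≤ 5 tips per tree
the DP's minimum cost and MPR count match exhaustive enumeration exactly,
and sampled MPR frequencies on a frozen two-optimum instance are uniform
within 3σ binomial bounds at 10,000 draws.

## RBS motif scanning

`frequency_table()` reproduces the published table structure: per dataset,
the number of sequences, annotated ORFs, ORFs with any Shine–Dalgarno
motif in the 24 nt upstream of the start codon, and the mutually
exclusive 4-mer/5-mer/6-mer classes. Decisions worth recording:

- **Longest-match precedence** (6 > 5 > 4): the source table never states
  exclusivity, but in every row the three class counts sum exactly to the
  total, which forces mutually exclusive classes with the hexamer
  dominating.
- Windows for non-first ORFs may overlap upstream coding sequence and are
  scanned anyway ("each annotated ORF", no exception); truncated windows
  (< 24 nt available for a non-first ORF) are shortened and flagged.
  Segments whose *first* ORF lacks a full 24-nt 5′ UTR are excluded by
  `filter_segments()` up front.
- Matches must lie wholly inside the extracted window (no overlap with
  the start codon); ambiguity codes never match; the first codon of a CDS
  is taken as the start codon without requiring ATG, since alternative
  genetic codes occur in these families.
- Percentages are 100 × count / n_orfs rounded **half-up** to one decimal
  (base R's `round()` is half-even and would disagree at .x5 boundaries).
- Input is FASTA + GFF3 (CDS features); minus-strand ORFs are
  reverse-complemented into plus orientation with a warning. GenBank flat
  files are not parsed: no installed parser exists in this R stack and
  format parsers are deliberately not hand-rolled here.

A documented reason the package reports *computed* values rather than
replicating any specific published table verbatim: the reference table
for this analysis contains internal inconsistencies (a 6-mer percentage
printed as 69.2 where the counts give 69.3, an ORF denominator of 3,219
where the matching text uses 3,251, and a segment count of 15 vs 17).
The scanner's arithmetic is checked instead against its own planted
ground truth and against the rows of that table that are internally
consistent.

## Simulators: what they emulate, and what they do not

All generators are bit-for-bit reproducible from (parameters, seed).

- `simulate_cophylogeny()` is a generative mirror of the undated DTL
  model: a virus lineage descends the host tree, and at each bifurcation
  co-diverges, transfers (recipient uniform among non-ancestral host
  nodes), duplicates, or dies, with the stated probabilities
  (renormalized at the host root, where no transfer recipient exists).
  Duplicated/staying lineages re-draw at the same node, so event counts
  per realized internal virus node are exact by construction. Default
  condition for recovery experiments: 16-tip Yule hosts, transfer rates
  0.05–0.5, tip cap 4× the host size. It does **not** simulate sequence
  evolution, inference error, or branch-length noise — so recovery tests
  show the statistics behave correctly on true trees, not that they are
  robust to tree-estimation error.
- `simulate_ensemble()` plants long-stem clusters (stems 1.0 vs internal
  branches ≤ 0.05, i.e. well above the stem-factor threshold) with
  supports drawn in [90, 100] inside clusters and [50, 79] on the
  backbone, and relocates each migrant tip onto a *foreign cluster's
  stem* in at least one tree. Regrafting onto the stem rather than inside
  the foreign clade keeps every cluster's purity at 1, which makes
  "exactly the migrants become unclassified" a theorem of the
  construction rather than a tuning outcome. Real ensembles differ in
  ways this does not model: correlated topological error, rogue taxa
  moving within clusters, and support values that covary with clade size.
- `simulate_segments()` plants one motif of the drawn class into
  background sequence rejection-sampled to contain no Shine–Dalgarno
  4-mer (every longer motif contains one of the 4-mers, so excluding the
  three 4-mers excludes everything), then verifies the planted window
  against `classify_window()` — scanner tests are therefore exact, not
  statistical. The deterministic-count mode drives the worked
  published-table reproductions. Real segments have non-uniform base
  composition and motif spacing preferences; neither matters to a
  windowed exact-match scanner, which is why the simplification is
  acceptable here.

## Numerical and determinism choices

- Floating-point cost ties in the DP use a 1e-9 absolute tolerance
  (costs are small integers or user rationals, so this is safe).
- Midpoint ties: lexicographically smallest sorted tip pair. Membership
  ties: most members, then purity, then clade size, then smallest tip
  set. Host polytomy resolution: `ape::multi2di` under the caller's seed,
  returned for audit.
- All sampling (`nph85` resampling, MPR draws, every simulator) takes an
  explicit seed and restores the caller's RNG state afterwards.
- Problem sizes used by the shipped tests: reconciliation oracle
  equivalence on 200 random ≤ 5-tip instances; rate recovery on 10
  transfer levels × 20 replicates on 16-tip hosts; classification
  recovery on 10-tree ensembles of 40 tips; scanner reproductions on
  687- and 782-ORF compositions. These sizes make the full suite run in
  well under a minute while keeping every check non-trivial.

## Known limitations

- The published family-scale quantities (nPH85 of 0.998 over 1,269
  animal-associated viruses, 68 % transfer likelihood, the 2,125-core
  assignment over 2,286 sequences) require the GenBank-derived trees and
  alignments, which are inputs, not outputs, of this package; the
  pipeline accepts such trees when a user supplies them, and the
  property-based tests cover the same behaviours at desk scale.
- The DTL model is undated and parsimony-based: no likelihoods, no Pareto
  exploration of cost regimes, no dated-transfer feasibility.
- MPR counts above 2^53 would lose exactness (doubles); no
  arbitrary-precision integers.
- One support value per internal edge is assumed; the expanded-host-tree
  nPH85 mode inherits the host cladogram's polytomies as hard structure.
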