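---
title: "Methods: synteny networks for focal gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny networks for focal gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntnet)
```

## The model

A synteny network describes a focal gene family across genomes as a
weighted undirected graph. Vertices are *tandem gene regions*: maximal
groups of focal genes on one chromosome connected by tandem-duplicate
calls (connected components of the union of calls over all detection
methods), with never-called focal genes as singleton regions. Edges
denote detected collinearity between the regions' neighbourhoods.
Because collinearity detection depends on two upstream choices — the
detector and the homology clustering that defines anchors — the network
aggregates a 2 × 2 evidence grid (two detectors × two clusterings). Each
combination that reports a syntenic link between two regions contributes
0.25 to the edge weight, so weights take values 0.25–1.0 and encode
evidence strength, not block quality.

Two of the four combinations form what we call *crossed pairs*: support
sets in which the two detectors agree only under different clusterings
({detector₁+clustering₁, detector₂+clustering₂} and the converse). Such
agreement is ambiguous — it cannot be attributed to either a robust
detector result or a robust clustering — and edges whose support equals
exactly a crossed pair are removed. We remove on *exact* support-set
match: a three- or four-method support set that merely contains a
crossed pair also contains a concordant detector pair and is kept. The
alternative reading (subtracting crossed contributions from every edge)
is available behind `build_network(cross_removal = "none")` plus manual
filtering; we did not adopt it as a default because it would zero out
fully supported edges. Vertices left isolated after the filter are
dropped.

### Assumptions

* Gene order within a chromosome is a total order (ordinal ranks; real
  coordinates are discarded on input).
* Anchors are family-level matches: two positions anchor if their genes
  share a family, regardless of strand (strand is read and stored but
  does not constrain chaining).
* Within-block order is strict: a-positions strictly increase and
  b-positions are strictly monotone with a single sign per block.

## Collinearity detection

One chaining algorithm serves both detector profiles. Anchors of a
chromosome pair are sorted by a-position; a dynamic program finds, for
every anchor, the best chain ending there subject to: per-step gaps of at
most `max_gap` intervening genes on both genomes, a per-block total of at
most `max_gaps_total` skipped genes, and a score
`match_score · n_anchors + gap_penalty · skipped`. The program is layered
over (anchor, total skipped, saturating chain length), so the best block
honouring the `min_anchors` threshold is found exactly; blocks are
extracted greedily by descending score (ties: smaller first a-ordinal,
then forward orientation) with the dynamic program re-run on the
remaining anchors, so each anchor joins at most one block. The
implementation is in C++ and is checked in the test suite against
brute-force enumeration of all valid anchor subsets on instances of up to
12 anchors.

The two profiles fix `min_anchors = 5`, `match_score = 50` and
`gap_penalty = −1`, and differ in the gap geometry: the MCScanX-like
profile allows `max_gap = 25` and 25 total skips; the i-ADHoRe-like
profile allows `max_gap = 15` and 20 total skips. Neither profile
reproduces the original tools' block significance statistics (E-value
models, probabilistic cloud filters); when those matter, the native
output files can be parsed directly (`parse_mcscanx_collinearity()`,
`parse_iadhore_output()`, the latter restricted to level-2 multiplicons)
and fed into the same network stage. For self-comparisons of a
chromosome, identity anchors are excluded and each unordered anchor pair
is enumerated once, so intragenomic duplications are detected without
mirror-duplicate blocks.

Tandem calls are same-chromosome, same-family pairs separated by at most
`tandem_gap` intervening genes (default 1 per profile — the underlying
tools differ in their tandem conventions, so this is a profile parameter
rather than a constant).

## Homology clustering

The similarity transform is `min(−log10 E, 200)`, clamped below at 0; an
E-value of 0 (or any value at or below 1e−200) receives the ceiling 200.
Markov clustering then alternates expansion (matrix squaring of the
column-stochastic matrix) and inflation (entrywise power 2, column
renormalisation). Numerical choices: self-loops equal to each node's
maximum incident similarity are added before normalisation (standard
regularisation; prevents oscillation on near-bipartite graphs); the
iteration stops when the maximum absolute matrix change falls below
1e−6, capped at 100 iterations with a warning; entries below 1e−8 are
pruned after each inflation purely to preserve sparsity (the matrices
are kept sparse so a few thousand genes cluster in seconds). Attractor
rows (positive diagonal in the limit) seed clusters; nodes join the
attractor they flow to most, ties to the smaller index, and attractors
sharing support merge. The dense reference iteration used as the test
oracle is an independent implementation kept in the test helpers.

## Consensus clustering

Four igraph community algorithms partition the weighted network: greedy
modularity, short random walks (steps = 15), leading eigenvector
(steps = 15) and multi-level modularity. Each runs under a fixed internal
RNG state, so the ensemble is deterministic given the vertex ordering;
an algorithm failing on a degenerate graph falls back to connected
components with a message.

The four partitions are combined into pairwise distances: per vertex
pair, each algorithm contributes 0 (same community) or 1 (different),
and the four binaries are averaged, giving d ∈ {0, 0.25, 0.5, 0.75, 1}.
Averaging is the minimal way to feed "the information from all four
algorithms" into one exemplar-based step; sums or squared counts would
only rescale the affinity-propagation input monotonically.

Affinity propagation on similarity = −d consolidates the ensemble:
standard responsibility/availability message passing with damping 0.9,
a convergence window of 1000 unchanged-exemplar iterations, and a cap of
10000 iterations. The exemplar preference defaults to the median
off-diagonal similarity (configurable). No random noise is injected.
Noise-free message passing oscillates on exactly symmetric inputs — the
situation our quantised distances create routinely — so symmetry is
broken deterministically instead: an infinitesimal preference penalty
(10⁻⁶ of the similarity scale, increasing with vertex index) implements
the rule that ties go to the lower-indexed vertex. This keeps the
procedure deterministic and order-invariant after canonical relabelling
(cluster ids are assigned in exemplar order). At small n the solution's
net similarity is verified in the tests against exhaustive enumeration
of all exemplar subsets.

Affinity propagation runs globally even when the network is
disconnected (between-component distances are typically 1), matching a
single global distance matrix; within large ensemble communities it can
subdivide further, which is why the consensus may be finer than any
single algorithm's partition.

## Enrichment statistics

Reaction-type enrichment selects clusters with strictly more than 15%
focal-type genes and at least 10 genes (region members count
individually), builds the 2 × 2 table of focal-type versus other genes
inside versus outside the selected clusters — restricted to genes present
in the network — and applies a one-sided (greater) Fisher exact test. The
odds ratio reported is the conditional maximum-likelihood estimate (the
convention of R's `fisher.test`), with the sample odds ratio `ad/bc` as a
secondary column. Degenerate all-zero tables return p = 1 and an NaN
odds ratio with a flag.

GO enrichment treats annotations as flat term sets (no ontology-graph
propagation — annotations are consumed as produced by upstream
annotation servers; propagation is deliberately out of scope). Per
design (focal regions vs all syntenic genes or all genes; type-enriched
clusters vs background; type-enriched clusters vs focal regions),
Benjamini–Hochberg correction is applied across the tested terms of that
design only, and focal genes can be excluded from both sides with
`exclude`. Term relationships use the enrichment-map convention:
½ Jaccard + ½ overlap coefficient on foreground gene sets, keeping edges
at or above 0.375 among terms with q < 0.2.

The test suite checks the Fisher implementation against direct
binomial-coefficient enumeration over all tables with row margins up to
30, and the selection-plus-test pipeline against label-shuffled nulls:
with a universe of 400 genes, 80 focal-type labels and 120 genes inside
the selected clusters, the attainable size of the discrete test at
α = 0.05 is 0.0397, so the rejection rate over 1000 shuffles is required
to fall in 0.05 ± 0.02. The universe dimensions were chosen a priori so
that discreteness keeps the attainable size near the nominal level; with
very small tables the exact test is far more conservative and no such
check is informative.

## The simulator: what it emulates and what it does not

`simulate_evolution()` grows a single ancestral genome (default
3 chromosomes × 200 genes, 150 background families) along a species tree
(default: a random 6-leaf tree). The focal family is planted as two
copies in well-separated neighbourhoods — two ancestral *syntenic
contexts*, the ground truth that downstream clustering should recover.
On every branch, in fixed order: whole-genome duplication (probability
per branch), segmental duplications (Poisson, default 0.5/branch,
windows of 8 genes), gene losses (1/branch), inversions (0.5/branch),
translocations (0.25/branch), and tandem duplications last
(2/branch, biased 50:50 toward focal genes, arrays capped at 23 copies —
the largest array size reported for this family in real genomes).
Duplication of a focal gene opens a new context (recorded in
`truth_regions`); tandem copies inherit their parent's context, since a
tandem array is one region by definition.

Determinism and coupling: every (branch, event type) pair has its own
random stream derived from the master seed, and event counts are drawn
by Poisson inversion, so raising one rate leaves the other events'
streams untouched and can only append events — the basis of the
monotonicity property tested for tandem duplication. Identical
configurations produce bit-identical datasets.

The E-value model for `simulate_similarity_graph()` is
log10 E = −50 + Normal(0, noise) within families, with a small rate of
spurious cross-family hits at E ∈ (0.1, 10], clipped to (1e−300, 10].
Only the transformed ordering matters downstream, so the absolute scale
is arbitrary. `perturb_family_assignment()` derives a second, imperfect
clustering by random family merges and splits, emulating the
disagreement between two independent homology pipelines that motivates
the 2 × 2 evidence grid.

What the simulator does *not* emulate: sequence evolution (no
nucleotides or proteins, hence no alignment artefacts), selection,
lineage-specific erosion-rate variation, assembly fragmentation, or
annotation error beyond the explicit merge/split perturbation. Passing
tests on simulated data therefore demonstrate correctness of the
pipeline's logic under its stated model — planted structure in, planted
structure out — not robustness to every pathology of real genome
annotations. Simulator defaults are desk-scale by design and are not
calibrated to any specific published genome collection.

## Problem sizes and runtime

Defaults are sized so a full pipeline run takes seconds: 6 species ×
600 genes gives a similarity graph of ~45k edges (sparse MCL, ~7 s) and
~190 chromosome-pair comparisons per detector/clustering combination
(C++ chaining, ~3 s total). The repeated-seed tests (20-seed structure
recovery) use a reduced configuration — 4 species, 2 chromosomes × 120
genes, 60 families — which preserves the two-context structure while
keeping each run under ~3 s; the vignette states these sizes as the
package's own choice of test scale. In one of the 20 seeds the random
gene losses delete every descendant of one planted context; the
recovery test asserts cluster purity always, and the two-cluster outcome
only when both contexts survive to the network, since the premise of the
scenario no longer holds otherwise.

## Known limitations

* The emulated detectors share one chaining engine; differences between
  the real MCScanX and i-ADHoRe beyond gap geometry (statistical block
  filters, overlap merging) are not modelled. Imported native outputs
  bypass this limitation.
* Whether the original crossed-pair filter removed edges by exact
  support match or subtracted contributions is ambiguous in prose
  descriptions of such workflows; exact match is our documented choice.
* Affinity propagation on a quantised distance matrix can be sensitive
  to the preference; the median default reproduces the expected
  refinement behaviour but other preferences change cluster counts.
* GO enrichment ignores the ontology graph (no term propagation) and
  treats annotation sets as exact.
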