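---
title: "Methods: metric backbones, the orthoBackbone, and phylostratigraphy in obkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metric backbones, the orthoBackbone, and phylostratigraphy in obkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obkit)
```

# What the toolkit computes

obkit analyses weighted gene interaction networks across species. The
motivating setting is comparative transcriptomics of a conserved cell
type: expression data define which genes are active, a confidence-scored
interaction database defines the weighted network among them, orthogroups
connect the genes of different species, and a rooted species tree dates
each orthogroup. From these the toolkit derives

1. per-gene **phylostrata** and the **transcriptome age index (TAI)**,
2. per-species filtered **network layers** and their **metric backbones**,
3. the cross-species **orthoBackbone**, and
4. node-connectivity statistics, conservation classifiers, and an
   edge-disruption statistic for differentially expressed gene (DEG) sets.

Every stage is runnable on the built-in synthetic generator, so the whole
pipeline is testable without external databases.

# Phylostratigraphy and the transcriptome age index

`rankTree()` numbers the nodes on the root-to-focal-species path of a
rooted tree 1..K: rank 1 is the root (oldest clade), rank K the focal
leaf (species-specific). The tree must have a bifurcating root;
multifurcations elsewhere are allowed, and each path node still receives
exactly one rank.

`assignPhylostrata()` assigns each orthogroup containing a focal-species
gene to the most recent common ancestor of all species with members.
Because the focal species is among them, that node lies on the ranked
path; all focal genes of the orthogroup inherit its rank. Genes absent
from every orthogroup (orphans), and focal-only orthogroups, receive rank
K — the usual phylostratigraphy convention for lineage-restricted genes.
The source text we reimplement does not state its orphan handling; this
default is the package's own choice and is explicit in the API
(`orphanGenes`).

The TAI of a sample is the expression-weighted mean rank of its expressed
genes,

$$\mathrm{TAI} = \frac{\sum_i r_i\,\mathrm{TPM}_i}{\sum_i \mathrm{TPM}_i},$$

so higher values indicate younger transcriptomes. It is invariant under
positive rescaling of expression and monotone in any included gene's
rank. Two choices are configurable because conventions differ:

* **Expression cutoff.** Genes enter the TAI only with mean TPM
  strictly above `cutoff` (default 1, matching the "minimum average
  TPM > 1" convention for calling a gene expressed; classic TAI uses all
  genes with nonzero expression, i.e. `cutoff = 0`).
* **Per-sample vs per-group.** Whether the index is computed per sample
  (then averaged per group) or directly on per-group mean TPM is not
  fixed by convention; both are exposed (`by = "sample"` / `"group"`).

`conservedFraction()` reports, per group, the fraction of expressed genes
whose rank falls in `oldRanks` (default 1–5, the strata shared by all
Metazoa in a 16-stratum vertebrate analysis; pass the set that matches
your tree), with an optional two-sided Mann–Whitney U test between two
groups' per-sample fractions.

# Network layers

`expressedGenes()` applies the strict mean-TPM filter (a gene at exactly
the cutoff is excluded). `buildLayer()` keeps an interaction iff both
endpoints are expressed and the confidence score is **at least**
`minScore` (default 0.5 on the unit scale; the source conventions state
"score ≥ 0.5" in one place and "< 0.5 removed" in another, which differ
only at exactly 0.5 — the inclusive reading is used). Scores on the
0–1000 integer convention are normalized by `readEdges()`; its `"auto"`
mode selects the thousand scale iff any score exceeds 1, since unit-scale
scores cannot. Duplicate undirected edges collapse to the **maximum**
score (conservative retention of the strongest evidence, and
deterministic); self-edges are dropped with a message.

`largestComponent()` mirrors the common display convention of analysing
the largest connected component. Ties (which never occur on real data)
are broken deterministically in favour of the component whose sorted node
list is lexicographically smallest. LCC extraction is optional: the
backbone is computed component-wise anyway.

# The metric backbone

Confidence scores are proximities; shortest paths need distances.
`toDistance()` uses the nonlinear isomorphism

$$d = \frac{1}{s} - 1,$$

the standard choice in the metric-backbone literature for weights in
(0, 1]: it maps full confidence to distance 0 and is strictly
decreasing. `-log s` and `1 - s` are available for sensitivity analyses
(the backbone depends on the transform, because path lengths add).

An edge is **semi-metric** when it is strictly longer than some indirect
path between its endpoints; it then lies on no shortest path and can be
removed without changing any shortest-path distance. The **metric
backbone** keeps all nodes and exactly the metric edges. Numerical
choices:

* **Ties are metric.** An indirect path exactly equal to the direct
  distance keeps the edge. The backbone must realize at least one
  shortest path per pair, and counting ties as metric also makes the
  operation idempotent.
* **Tolerance.** Comparisons use a relative tolerance of `1e-9`
  (distances are only a few arithmetic operations deep); it is exposed as
  `relTol`.
* **Algorithm.** Classification compares each direct distance with the
  all-pairs shortest-path distance, computed by Dijkstra from every node
  via igraph. The test suite checks the labelling against an independent
  Floyd–Warshall implementation on hundreds of random graphs, and
  `verifyDistancePreservation()` re-checks the defining property on any
  result.

# The orthoBackbone

`linkLayers()` connects genes of the same orthogroup across layers
(one-to-many: paralogs all link), and flags a node conserved iff its
orthogroup has at least one member node in every layer.
`extractOrthoBackbone()` then keeps a backbone edge $(a, b)$ of layer $L$
iff **every** other layer contains a backbone edge $(a', b')$ with $a'$
an ortholog of $a$, $b'$ an ortholog of $b$, and $a' \ne b'$. With
paralogs the mapping is one-to-many and a single analogous backbone edge
suffices. Nodes left without retained edges are removed, so the
orthoBackbone usually has fewer nodes than its layer and is not itself a
metric backbone.

Two design points the source text leaves open:

* **Within-orthogroup edges.** An edge between two paralogs of one
  orthogroup would map onto a single gene in a 1:1 layer; we require
  $a' \ne b'$, so such an "analog" does not count. Intra-layer paralog
  edges are otherwise ordinary edges.
* **Backbone, not fixed point.** The analog edge must be in the other
  layer's *metric backbone*, not in its orthoBackbone. A fixed-point
  variant (iterating until mutual support stabilizes) would be stricter;
  the text describes the backbone criterion, which is what is built. The
  result is independent of layer order, pairwise orthoBackbones are
  supersets of three-way ones (the all-other-layers condition tightens),
  and the implementation is tested against brute-force enumeration.

`selectCore()` reduces an orthoBackbone layer to edges touching genes in
the intersection of two annotation sets (default reading of "a
spermatogenesis-related gene linked to gene expression regulation"); a
one-endpoint-per-set mode is available. `edgeDisruption()` counts edges
with at least one endpoint in a DEG set, and `disruptionTest()` compares
two such fractions with a two-sided Fisher exact test.

# Features, null model, classifiers

`nodeFeatures()` computes degree centrality ($\deg/(n-1)$) and PageRank
(damping 0.85, unweighted topology — the standard defaults; the source
names no others). `ksCompare()` contrasts conserved vs non-conserved
feature distributions with a two-sample two-sided KS test.

`rewireLayer()` is the ascertainment-bias control: a chosen fraction of
edges is deleted and replaced by uniformly random pairs (rejecting loops
and duplicates), preserving node set, edge count, simplicity, and the
score multiset. The rewiring is deliberately **not** degree-preserving —
the point is to measure how degree-linked signals decay as wiring is
randomized, which a degree-preserving swap cannot show.

`classifyConservation()` runs stratified k-fold (default 4) cross-
validation of a random forest (100 trees, default depth) or a linear SVM
(cost 1, features standardized per training fold), reporting per-fold and
mean ROC AUC plus pooled out-of-fold precision–recall points. The feature
vector defaults to the two reported connectivity features. Hyperparameters
are fixed, recorded in the report, and deliberately unremarkable: the
published AUCs for this kind of task (≈0.74–0.82 on real cell-type
networks) are qualitative anchors, not targets, because the exact feature
set and hyperparameters behind them are unstated.

# The synthetic generator

`simulateMultilayer()` emulates the statistical structure the pipeline
assumes, with planted ground truth:

* **Conserved core.** A configurable fraction of genes (default 0.5,
  matching the roughly half of cell-type network genes that are
  metazoan-conserved) belong to orthogroups spanning every layer, with a
  second copy per layer at `paralogRate` (default 0.3).
* **Elevated connectivity.** Each layer is a Chung–Lu expected-degree
  graph; conserved genes get `degreeMultiplier` (default 3) times the
  background mean degree (default 10 — desk-scale; real cell-type
  networks are denser).
* **Interologs.** A single core edge set over conserved orthogroups is
  planted identically in every layer, supplying `interologRate` (default
  0.3) of a conserved gene's elevated expected degree; the Chung–Lu
  residual of primary copies is reduced by the same amount, so expected
  degrees — and the chance-level classification property at
  `degreeMultiplier = 1` — are unchanged. Without this, independently
  wired layers share analogous backbone edges only by chance and the
  orthoBackbone is empty by construction; conserved interactomes have
  interologs, and this is what the collapse detects. Paralog copies are
  wired independently at the full rate (derived copies carrying fewer
  ancestral interactions).
* **Phylostrata.** The species tree is a caterpillar with `sp1` focal, so
  K equals the layer count. Conserved orthogroups map to the root
  (rank 1); `partialFraction` of genes sit in orthogroups spanning a
  proper species prefix (intermediate ranks); remaining genes are
  species-specific — half in singleton orthogroups, half orphans absent
  from the table, exercising both rank-K paths.
* **Scores** are Beta(4, 2) (right-skewed; most pass the 0.5 confidence
  filter), truncated to (0, 1].
* **Expression** (`simulateExpression()`) is log-normal with a per-stage
  log-mean shift proportional to a gene's centered rank
  (`stageAgeSlope`, default 0.5, over 3 stages × 3 replicates), so the
  planted TAI increases across stages.
* **DEG sets** (`simulateDeg()`) sample a fraction of genes, optionally
  with an odds bias toward the conserved core.

One global seed drives derived per-component seeds, so any stage is
reproducible in isolation and two runs with one seed are byte-identical
through the whole file-level pipeline.

What the generator does **not** emulate: community/module structure,
heavy-tailed degree distributions beyond the two-tier core/background
contrast, correlated evidence channels behind confidence scores,
cross-layer score correlation on planted interologs, and realistic
paralog divergence. Passing tests therefore demonstrate correctness of
the algorithms and recoverability of planted signals — not that real
interactomes satisfy the generator's assumptions.

# Problem sizes and determinism

The shipped test suite validates the backbone classification on 200
random graphs (≤ 50 nodes) against Floyd–Warshall, the orthoBackbone on
100 random 2–3-layer toys (≤ 30 nodes/layer) against enumeration,
phylostratigraphy on 100 random trees (≤ 12 leaves) against a clade-scan
oracle, and classification recovery at 2000 genes/layer — sizes chosen so
the full suite runs in about a minute while keeping every estimate's
Monte-Carlo error far from its acceptance band. `scripts/acceptance.R`
re-runs the full pipeline at the default study conditions (3 layers,
2000 genes/layer) and reports its headline quantities as JSON.

All stochastic functions take explicit seeds; file outputs carry a
version header but no timestamps, and every pipeline run writes a
manifest (inputs with checksums, parameters, seed) sufficient to
reproduce it exactly.

# Known limitations

* Gene identifiers are opaque strings; reconciling database namespaces
  (e.g. protein vs gene ids) is an upstream concern.
* The backbone scales as all-pairs Dijkstra; million-edge layers need the
  pruned variants from the literature, which are out of scope.
* The orthoBackbone is computed on topology only; edge weights are not
  compared across layers.
* `conservedFraction()`'s default `oldRanks = 1:5` presumes a deep tree;
  choose the set to match your ranked path.
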