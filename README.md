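# obkit

Cross-species analysis of weighted gene interaction networks: metric
backbones, the multilayer **orthoBackbone**, phylostratigraphy, and the
statistics that sit around them.

## The problem

Comparing a cell type's interactome across distant species asks two
questions at once: *how old* is its gene expression program, and *which
interactions* are part of a conserved core rather than species-specific
wiring? obkit is for computational biologists who have, per species, a
TPM expression table, a confidence-scored interaction list (STRING-style
combined scores), an orthogroup table (OrthoFinder `Orthogroups.tsv`
dialect), and a rooted species tree — and want reproducible, testable
answers to both.

## The methods

**Phylostratigraphy / TAI.** The root-to-focal path of the species tree
is ranked 1..K (1 = oldest). Each orthogroup maps to the most recent
common ancestor of its member species; focal genes inherit that rank. The
transcriptome age index of a sample is the expression-weighted mean rank

    TAI = Σᵢ rᵢ · TPMᵢ / Σᵢ TPMᵢ ,

higher meaning younger.

**Metric backbone.** Confidence scores s ∈ (0, 1] become distances
d = 1/s − 1. An edge is *semi-metric* when it is strictly longer than
some indirect path between its endpoints — it lies on no shortest path
and is redundant. The metric backbone keeps all nodes and exactly the
metric edges; it is the smallest subgraph sufficient to compute every
shortest path of the network.

**orthoBackbone.** Given one backbone per species plus interlayer
ortholog links, a backbone edge (a, b) survives iff *every* other layer
has a backbone edge (a′, b′) between orthologs of a and b (a′ ≠ b′; with
paralogs, one analogous edge suffices). Nodes left without edges are
dropped. The result is the cross-species conserved interaction core,
per layer.

**Downstream.** Degree centrality and PageRank per node,
Kolmogorov–Smirnov comparisons of conserved vs non-conserved genes,
cross-validated random-forest / linear-SVM conservation classifiers, a
uniform edge-rewiring null, Jaccard edge overlap, annotation-based core
selection, and the DEG edge-disruption fraction with Fisher tests.

A seeded synthetic generator (`simulateMultilayer()` and friends) plants
a conserved core with elevated connectivity and mirrored interologs,
paralogs, phylostratum structure, an age-by-stage expression trend, and
DEG sets — so the full pipeline runs and is tested without any external
database.

## A worked example

```r
library(obkit)

cfg <- simulationConfig(nLayers = 3, genesPerLayer = 300,
                        meanDegree = 8, seed = 42)
sim <- simulateMultilayer(cfg)
sim$layers$sp1
#> Layer 'sp1': 300 nodes, 2725 edges (198 conserved nodes)

ml <- computeBackbones(linkLayers(sim$orthogroups, sim$layers))
mlBackbones(ml)$sp1
#> BackboneResult of layer 'sp1': 1202/2725 edges metric (44.1%), 1523 semi-metric

ob <- extractOrthoBackbone(ml)
ob
#> OrthoBackbone:
#>   sp1: 42 edges over 63 nodes
#>   sp2: 42 edges over 62 nodes
#>   sp3: 42 edges over 63 nodes

rt <- rankTree(sim$tree, "sp1")
ps <- assignPhylostrata(sim$orthogroups, rt,
  orphanGenes = subset(sim$truth$genes, species == "sp1")$gene)
expr <- simulateExpression(sim$truth)
round(tai(expr$se, ps, by = "group")$groups$tai, 3)
#> [1] 1.629 1.746 1.847

deg <- simulateDeg(sim$truth)
unlist(edgeDisruption(obEdges(ob, "sp1"), deg))
#>      total  disrupted   fraction
#> 42.0000000  9.0000000  0.2142857

ft <- nodeFeatures(sim$layers$sp1)
round(classifyConservation(ft, "random-forest", seed = 1)$mean_auc, 3)
#> [1] 0.99
```

Reading the output: over half of this layer's edges are semi-metric and
prunable without changing any shortest path; 42 backbone edges have
analogous backbone edges in both other species — the conserved core; the
transcriptome gets younger stage by stage (TAI 1.63 → 1.85, driven by the
planted trend); 21% of core edges touch a simulated DEG; and connectivity
features alone recover the planted conserved labels almost perfectly.

On real inputs, replace the simulated pieces with `readExpression()`,
`readEdges()`, `readOrthogroups()` and a Newick tree, then
`expressedGenes()` → `buildLayer()` → the same chain. A file-level
interface with fixed output names and run manifests is available through
`runSubcommand()` and the `inst/scripts/obkit` command-line wrapper.

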