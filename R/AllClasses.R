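setOldClass("igraph")
setOldClass("phylo")

#' Ranked species tree
#'
#' A rooted species tree whose root-to-focal-leaf path has been ranked into
#' phylostrata: rank 1 is the root (oldest clade), rank K the focal leaf
#' (species-specific). Construct with [rankTree()].
#'
#' @slot tree a rooted `ape::phylo` object.
#' @slot focal the focal species, a leaf label of `tree`.
#' @slot pathNodes integer vector of internal/tip node indices along the
#'   root-to-focal path, in root-to-leaf order; position i has rank i.
#' @slot K number of phylostrata (length of `pathNodes`).
#'
#' @seealso [rankTree()], [assignPhylostrata()], [strataRanks()]
#' @export
setClass("RankedSpeciesTree",
  representation(tree = "phylo", focal = "character",
                 pathNodes = "integer", K = "integer"))

setValidity("RankedSpeciesTree", function(object) {
  msg <- character()
  if (length(object@focal) != 1L || !object@focal %in% object@tree$tip.label)
    msg <- c(msg, "focal species must be a single leaf of the tree")
  if (length(object@pathNodes) != object@K)
    msg <- c(msg, "K must equal the ranked path length")
  if (anyDuplicated(object@pathNodes))
    msg <- c(msg, "each node on the ranked path carries exactly one rank")
  if (length(msg)) msg else TRUE
})

#' Single-species weighted interaction layer
#'
#' One species' undirected simple graph with per-edge confidence scores in
#' (0, 1] and derived distances, plus an optional per-node conservation
#' flag. Construct with [buildLayer()] or from a simulation.
#'
#' @slot species species identifier.
#' @slot graph an undirected simple `igraph` with edge attributes `score`
#'   and `distance` and (optionally) a logical vertex attribute `conserved`.
#'
#' @seealso [buildLayer()], [metricBackbone()], [nodeFeatures()]
#' @export
setClass("Layer", representation(species = "character", graph = "igraph"))

setValidity("Layer", function(object) {
  g <- object@graph
  msg <- character()
  if (length(object@species) != 1L || is.na(object@species))
    msg <- c(msg, "species must be a single identifier")
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (igraph::any_loop(g)) msg <- c(msg, "graph must have no self-loops")
  if (igraph::any_multiple(g)) msg <- c(msg, "graph must have no parallel edges")
  if (igraph::ecount(g) > 0) {
    s <- igraph::edge_attr(g, "score")
    d <- igraph::edge_attr(g, "distance")
    if (is.null(s) || any(!is.finite(s)) || any(s <= 0) || any(s > 1))
      msg <- c(msg, "edge scores must lie in (0, 1]")
    if (is.null(d) || any(!is.finite(d)) || any(d < 0))
      msg <- c(msg, "edge distances must be finite and non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Metric-backbone decomposition of a layer
#'
#' Partition of a layer's edges into metric (shortest-path-sufficient) and
#' semi-metric (triangle-inequality-breaking) classes, together with the
#' backbone subgraph: all original nodes, metric edges only. Construct with
#' [metricBackbone()].
#'
#' @slot layer the input [Layer-class].
#' @slot metric logical vector aligned with the layer's edges; `TRUE` for
#'   metric edges.
#' @slot backbone the backbone `igraph` (all nodes, metric edges).
#'
#' @seealso [metricBackbone()], [verifyDistancePreservation()]
#' @export
setClass("BackboneResult",
  representation(layer = "Layer", metric = "logical", backbone = "igraph"))

setValidity("BackboneResult", function(object) {
  msg <- character()
  if (length(object@metric) != igraph::ecount(object@layer@graph))
    msg <- c(msg, "metric flags must align with the layer's edges")
  if (igraph::vcount(object@backbone) != igraph::vcount(object@layer@graph))
    msg <- c(msg, "backbone must retain all layer nodes")
  if (igraph::ecount(object@backbone) != sum(object@metric))
    msg <- c(msg, "backbone must contain exactly the metric edges")
  if (length(msg)) msg else TRUE
})

#' Multilayer network with interlayer ortholog links
#'
#' Species layers (with their metric backbones, once computed) plus the
#' interlayer links connecting genes of the same orthogroup across layers.
#' Construct with [linkLayers()]; add backbones with [computeBackbones()].
#'
#' @slot layers named list of [Layer-class] objects, one per species.
#' @slot backbones named list of [BackboneResult-class] objects (may be
#'   empty until [computeBackbones()] is called).
#' @slot links data.frame of interlayer links with columns `species_a`,
#'   `gene_a`, `species_b`, `gene_b`, `orthogroup`; stored once per
#'   unordered pair, semantically symmetric.
#' @slot orthogroups the long-format orthogroup table used to build links.
#'
#' @seealso [linkLayers()], [extractOrthoBackbone()]
#' @export
setClass("MultilayerNetwork",
  representation(layers = "list", backbones = "list",
                 links = "data.frame", orthogroups = "data.frame"))

setValidity("MultilayerNetwork", function(object) {
  msg <- character()
  if (!length(object@layers) || is.null(names(object@layers)))
    msg <- c(msg, "layers must be a non-empty named list")
  if (!all(vapply(object@layers, is, TRUE, class2 = "Layer")))
    msg <- c(msg, "every layer must be a Layer object")
  if (nrow(object@links) &&
      any(object@links$species_a == object@links$species_b))
    msg <- c(msg, "interlayer links must connect genes of different layers")
  if (length(object@backbones) &&
      !all(names(object@backbones) %in% names(object@layers)))
    msg <- c(msg, "backbones must be named after layers")
  if (length(msg)) msg else TRUE
})

#' orthoBackbone of a multilayer network
#'
#' Per species layer, the subset of metric-backbone edges that have an
#' analogous backbone edge (between orthologs of the two endpoints) in
#' every other layer; nodes left without retained edges are removed, so
#' the result typically has fewer nodes than its layer and is itself not
#' necessarily a metric backbone. Construct with [extractOrthoBackbone()].
#'
#' @slot edges named list (per species) of data.frames with columns
#'   `gene_a`, `gene_b`, `score`, `distance`.
#' @slot nodes named list (per species) of retained gene identifiers.
#'
#' @seealso [extractOrthoBackbone()], [selectCore()], [edgeDisruption()]
#' @export
setClass("OrthoBackbone",
  representation(edges = "list", nodes = "list"))

setValidity("OrthoBackbone", function(object) {
  msg <- character()
  if (!identical(names(object@edges), names(object@nodes)))
    msg <- c(msg, "edges and nodes must cover the same layers")
  for (sp in names(object@edges)) {
    e <- object@edges[[sp]]
    touched <- unique(c(e$gene_a, e$gene_b))
    if (!setequal(object@nodes[[sp]], touched))
      msg <- c(msg, sprintf(
        "layer %s: every retained node must have a retained edge", sp))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn RankedSpeciesTree-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "RankedSpeciesTree", function(object) {
  cat(sprintf(
    "RankedSpeciesTree: %d leaves, focal '%s', %d phylostrata (1 = root)\n",
    length(object@tree$tip.label), object@focal, object@K))
})

#' @describeIn Layer-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "Layer", function(object) {
  g <- object@graph
  cons <- igraph::vertex_attr(g, "conserved")
  cat(sprintf("Layer '%s': %d nodes, %d edges%s\n", object@species,
              igraph::vcount(g), igraph::ecount(g),
              if (!is.null(cons))
                sprintf(" (%d conserved nodes)", sum(cons, na.rm = TRUE))
              else ""))
})

#' @describeIn BackboneResult-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "BackboneResult", function(object) {
  m <- sum(object@metric); e <- length(object@metric)
  cat(sprintf(
    "BackboneResult of layer '%s': %d/%d edges metric (%.1f%%), %d semi-metric\n",
    object@layer@species, m, e, if (e) 100 * m / e else 0, e - m))
})

#' @describeIn MultilayerNetwork-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "MultilayerNetwork", function(object) {
  cat(sprintf(
    "MultilayerNetwork: %d layers (%s), %d interlayer links, backbones %s\n",
    length(object@layers), paste(names(object@layers), collapse = ", "),
    nrow(object@links),
    if (length(object@backbones)) "computed" else "not computed"))
})

#' @describeIn OrthoBackbone-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "OrthoBackbone", function(object) {
  cat("OrthoBackbone:\n")
  for (sp in names(object@edges))
    cat(sprintf("  %s: %d edges over %d nodes\n", sp,
                nrow(object@edges[[sp]]), length(object@nodes[[sp]])))
})
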