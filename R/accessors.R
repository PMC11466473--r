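#' @name accessors
#' @title Accessors for obkit classes
#'
#' @description Small accessor layer so downstream code never reaches into
#' slots: species and graph of a [Layer-class], the edge table of a layer,
#' backbone or orthoBackbone, the metric flags and backbone graph of a
#' [BackboneResult-class], and phylostratum ranks of a
#' [RankedSpeciesTree-class].
#'
#' @param x an obkit object (see individual functions).
#' @param species for [obEdges()]/[obNodes()]: which layer; `NULL` returns
#'   the per-layer list.
NULL

#' @rdname accessors
#' @return `layerSpecies()`: the species identifier of a layer.
#' @export
layerSpecies <- function(x) {
  stopifnot(is(x, "Layer"))
  x@species
}

#' @rdname accessors
#' @return `layerGraph()`: the underlying `igraph` of a layer (or of the
#'   layer inside a `BackboneResult`).
#' @export
layerGraph <- function(x) {
  if (is(x, "BackboneResult")) return(x@layer@graph)
  stopifnot(is(x, "Layer"))
  x@graph
}

#' @rdname accessors
#' @return `edgeTable()`: data.frame `gene_a`, `gene_b`, `score`,
#'   `distance` (plus `metric` for a `BackboneResult`).
#' @export
edgeTable <- function(x) {
  if (is(x, "BackboneResult")) {
    tab <- edgeTable(x@layer)
    tab$metric <- x@metric
    return(tab)
  }
  stopifnot(is(x, "Layer"))
  g <- x@graph
  if (igraph::ecount(g) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), distance = numeric(),
                      stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(g, names = TRUE)
  data.frame(gene_a = el[, 1], gene_b = el[, 2],
             score = igraph::edge_attr(g, "score"),
             distance = igraph::edge_attr(g, "distance"),
             stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @return `conservedNodes()`: named logical vector of per-node
#'   conservation flags (`NA`-free only after [linkLayers()]).
#' @export
conservedNodes <- function(x) {
  stopifnot(is(x, "Layer"))
  g <- x@graph
  flags <- igraph::vertex_attr(g, "conserved")
  if (is.null(flags)) flags <- rep(NA, igraph::vcount(g))
  setNames(as.logical(flags), igraph::V(g)$name)
}

#' @rdname accessors
#' @return `backboneGraph()`: the backbone `igraph` (all layer nodes,
#'   metric edges only).
#' @export
backboneGraph <- function(x) {
  stopifnot(is(x, "BackboneResult"))
  x@backbone
}

#' @rdname accessors
#' @return `metricFlags()`: logical vector aligned with `edgeTable(layer)`.
#' @export
metricFlags <- function(x) {
  stopifnot(is(x, "BackboneResult"))
  x@metric
}

#' @rdname accessors
#' @return `strataRanks()`: data.frame `rank`, `node`, `label` for the
#'   ranked root-to-focal path (labels for tips; internal nodes may be "").
#' @export
strataRanks <- function(x) {
  stopifnot(is(x, "RankedSpeciesTree"))
  tr <- x@tree
  ntip <- length(tr$tip.label)
  lab <- vapply(x@pathNodes, function(nd) {
    if (nd <= ntip) tr$tip.label[nd]
    else if (!is.null(tr$node.label)) tr$node.label[nd - ntip]
    else ""
  }, character(1))
  data.frame(rank = seq_len(x@K), node = x@pathNodes, label = lab,
             stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @return `mlLayers()` / `mlBackbones()` / `mlLinks()`: components of a
#'   [MultilayerNetwork-class].
#' @export
mlLayers <- function(x) {
  stopifnot(is(x, "MultilayerNetwork"))
  x@layers
}

#' @rdname accessors
#' @export
mlBackbones <- function(x) {
  stopifnot(is(x, "MultilayerNetwork"))
  x@backbones
}

#' @rdname accessors
#' @export
mlLinks <- function(x) {
  stopifnot(is(x, "MultilayerNetwork"))
  x@links
}

#' @rdname accessors
#' @return `obEdges()` / `obNodes()`: retained edges (data.frame) and nodes
#'   (character) of an [OrthoBackbone-class] layer.
#' @export
obEdges <- function(x, species = NULL) {
  stopifnot(is(x, "OrthoBackbone"))
  if (is.null(species)) return(x@edges)
  if (!species %in% names(x@edges))
    stop("no orthoBackbone layer for species '", species, "'")
  x@edges[[species]]
}

#' @rdname accessors
#' @export
obNodes <- function(x, species = NULL) {
  stopifnot(is(x, "OrthoBackbone"))
  if (is.null(species)) return(x@nodes)
  if (!species %in% names(x@nodes))
    stop("no orthoBackbone layer for species '", species, "'")
  x@nodes[[species]]
}
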