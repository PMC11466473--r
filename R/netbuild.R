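# From expression + scored edges to filtered single-species layers.

#' Genes expressed in a sample group
#'
#' Genes whose arithmetic-mean TPM across the group's samples is strictly
#' greater than `cutoff` (a gene at exactly the cutoff is excluded).
#'
#' @param se `SummarizedExperiment` with `tpm` assay and `group` column
#'   data.
#' @param group group label to select.
#' @param cutoff mean-TPM expression cutoff; default 1.
#' @return character vector of gene ids, with a `label` attribute.
#' @export
expressedGenes <- function(se, group, cutoff = 1) {
  groups <- as.character(SummarizedExperiment::colData(se)$group)
  if (!group %in% groups) stop("unknown group '", group, "'")
  m <- .meanTpm(se, which(groups == group))
  structure(as.character(names(m)[m > cutoff]), label = group)
}

#' Build a filtered interaction layer
#'
#' Induces the weighted interaction graph of one species on a set of
#' expressed genes: an edge is kept iff both endpoints belong to `genes`
#' and its confidence score is at least `minScore` (default 0.5, the
#' combined-confidence convention). Distances are derived from scores via
#' [toDistance()]. Nodes are the retained genes that touch at least one
#' retained edge, plus any `genes` present in the edge universe
#' (`keepIsolated = TRUE` keeps all of `genes` as nodes).
#'
#' @param edges data.frame `gene_a`, `gene_b`, `score`, as from
#'   [readEdges()].
#' @param genes character vector of expressed genes.
#' @param minScore minimum confidence score (inclusive); default 0.5.
#' @param species species identifier stored in the layer.
#' @param transform score-to-distance transform, see [toDistance()].
#' @param keepIsolated keep genes with no retained edge as isolated nodes
#'   (default `FALSE`).
#' @return a [Layer-class].
#' @export
buildLayer <- function(edges, genes, minScore = 0.5, species = "species",
                       transform = c("inverse", "neglog", "oneminus"),
                       keepIsolated = FALSE) {
  transform <- match.arg(transform)
  genes <- unique(as.character(genes))
  keep <- edges$gene_a %in% genes & edges$gene_b %in% genes &
    edges$score >= minScore
  sub <- edges[keep, , drop = FALSE]
  verts <- if (keepIsolated) genes else unique(c(sub$gene_a, sub$gene_b))
  g <- igraph::graph_from_data_frame(
    sub[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  g <- igraph::set_edge_attr(g, "score", value = sub$score)
  g <- igraph::set_edge_attr(g, "distance",
                             value = toDistance(sub$score, transform))
  new("Layer", species = species, graph = g)
}

# internal constructor from an igraph that already carries score/distance
.layerFromGraph <- function(g, species) {
  new("Layer", species = species, graph = g)
}

#' Largest connected component of a layer
#'
#' Induced subgraph on the component with the most nodes. Ties are broken
#' deterministically: among equally sized components the one whose sorted
#' node-id list is lexicographically smallest wins.
#'
#' @param layer a [Layer-class].
#' @return a [Layer-class] restricted to the largest component.
#' @export
largestComponent <- function(layer) {
  stopifnot(is(layer, "Layer"))
  g <- layer@graph
  if (igraph::vcount(g) == 0) {
    warning("empty graph: largest component is empty")
    return(layer)
  }
  comp <- igraph::components(g)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1) {
    keys <- vapply(cand, function(k)
      paste(sort(igraph::V(g)$name[comp$membership == k]), collapse = "\r"),
      character(1))
    cand <- cand[order(keys)[1]]
  }
  sub <- igraph::induced_subgraph(g, which(comp$membership == cand))
  .layerFromGraph(sub, layer@species)
}
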