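# Multilayer assembly and the orthoBackbone: connect genes of the same
# orthogroup across species layers, then keep, per layer, only the
# metric-backbone edges that have an analogous backbone edge (between
# orthologs of the two endpoints) in every other layer. With paralogs the
# mapping is one-to-many and the inclusion criterion is that at least one
# homologous edge is in the other layer's backbone.

.edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Assemble a multilayer network from layers and orthogroups
#'
#' Builds the interlayer links: for every orthogroup, every cross-layer
#' pair of member genes that are nodes of their respective layers is
#' linked. Each node's `conserved` flag is set iff its orthogroup has at
#' least one member node in every layer; genes in no orthogroup get zero
#' links and `conserved = FALSE`.
#'
#' @param og long-format orthogroup table (`orthogroup`, `species`,
#'   `gene`), as from [readOrthogroups()].
#' @param layers named list of [Layer-class] objects (names are species
#'   ids, which must appear in `og`).
#' @return a [MultilayerNetwork-class] (backbones not yet computed; see
#'   [computeBackbones()]).
#' @export
linkLayers <- function(og, layers) {
  stopifnot(is.list(layers), !is.null(names(layers)))
  species <- names(layers)
  missing <- setdiff(species, unique(og$species))
  if (length(missing))
    stop("species absent from the orthogroup table: ",
         paste(missing, collapse = ", "))
  nodeSets <- lapply(layers, function(l) igraph::V(l@graph)$name)
  sub <- og[og$species %in% species, , drop = FALSE]
  inLayer <- mapply(function(sp, gene) gene %in% nodeSets[[sp]],
                    sub$species, sub$gene)
  sub <- sub[as.logical(inLayer), , drop = FALSE]
  if (nrow(sub)) {
    m <- merge(sub, sub, by = "orthogroup", suffixes = c("_a", "_b"))
    m <- m[m$species_a < m$species_b, , drop = FALSE]
    links <- data.frame(species_a = m$species_a, gene_a = m$gene_a,
                        species_b = m$species_b, gene_b = m$gene_b,
                        orthogroup = m$orthogroup, stringsAsFactors = FALSE)
    spPerOg <- lapply(split(sub$species, sub$orthogroup), unique)
    conservedOg <- names(spPerOg)[lengths(spPerOg) == length(species)]
  } else {
    links <- data.frame(species_a = character(), gene_a = character(),
                        species_b = character(), gene_b = character(),
                        orthogroup = character(), stringsAsFactors = FALSE)
    conservedOg <- character()
  }
  rownames(links) <- NULL
  for (sp in species) {
    consGenes <- sub$gene[sub$species == sp &
                            sub$orthogroup %in% conservedOg]
    g <- layers[[sp]]@graph
    flags <- igraph::V(g)$name %in% consGenes
    layers[[sp]]@graph <- igraph::set_vertex_attr(g, "conserved",
                                                  value = flags)
  }
  new("MultilayerNetwork", layers = layers, backbones = list(),
      links = links, orthogroups = og)
}

#' Compute the metric backbone of every layer
#'
#' @param ml a [MultilayerNetwork-class].
#' @param relTol passed to [metricBackbone()].
#' @return `ml` with the `backbones` slot filled.
#' @export
computeBackbones <- function(ml, relTol = 1e-9) {
  stopifnot(is(ml, "MultilayerNetwork"))
  ml@backbones <- lapply(ml@layers, metricBackbone, relTol = relTol)
  ml
}

# gene -> orthologs lookup, per target layer, from the symmetric links
.linkMaps <- function(links, species) {
  maps <- list()
  for (spFrom in species) for (spTo in setdiff(species, spFrom)) {
    sel1 <- links$species_a == spFrom & links$species_b == spTo
    sel2 <- links$species_b == spFrom & links$species_a == spTo
    from <- c(links$gene_a[sel1], links$gene_b[sel2])
    to <- c(links$gene_b[sel1], links$gene_a[sel2])
    maps[[spFrom]][[spTo]] <- split(to, from)
  }
  maps
}

#' Extract the orthoBackbone
#'
#' Per layer, a metric-backbone edge `(a, b)` is retained iff for every
#' other layer there exist orthologs `a'` of `a` and `b'` of `b`, with
#' `a' != b'`, such that `(a', b')` is a backbone edge of that layer (the
#' one-to-many rule: with paralogs, one analogous backbone edge suffices).
#' Nodes left without retained edges are removed, so the orthoBackbone
#' typically has fewer nodes than its layer and is not itself necessarily
#' a metric backbone. The result does not depend on layer order.
#'
#' @param ml a [MultilayerNetwork-class] with backbones computed
#'   ([computeBackbones()]).
#' @return an [OrthoBackbone-class].
#' @export
extractOrthoBackbone <- function(ml) {
  stopifnot(is(ml, "MultilayerNetwork"))
  species <- names(ml@layers)
  if (!all(species %in% names(ml@backbones)))
    stop("every layer needs a computed backbone; run computeBackbones()")
  maps <- .linkMaps(ml@links, species)
  bbTabs <- lapply(species, function(sp) {
    bb <- ml@backbones[[sp]]
    g <- bb@backbone
    if (igraph::ecount(g) == 0)
      return(data.frame(gene_a = character(), gene_b = character(),
                        score = numeric(), distance = numeric(),
                        stringsAsFactors = FALSE))
    el <- igraph::as_edgelist(g, names = TRUE)
    data.frame(gene_a = el[, 1], gene_b = el[, 2],
               score = igraph::edge_attr(g, "score"),
               distance = igraph::edge_attr(g, "distance"),
               stringsAsFactors = FALSE)
  })
  names(bbTabs) <- species
  bbKeys <- lapply(bbTabs, function(t) .edgeKey(t$gene_a, t$gene_b))
  edges <- list(); nodes <- list()
  for (sp in species) {
    tab <- bbTabs[[sp]]
    others <- setdiff(species, sp)
    keep <- vapply(seq_len(nrow(tab)), function(i) {
      a <- tab$gene_a[i]; b <- tab$gene_b[i]
      for (spO in others) {
        candA <- maps[[sp]][[spO]][[a]]
        candB <- maps[[sp]][[spO]][[b]]
        if (is.null(candA) || is.null(candB)) return(FALSE)
        pairs <- expand.grid(candA, candB, stringsAsFactors = FALSE)
        pairs <- pairs[pairs[[1]] != pairs[[2]], , drop = FALSE]
        if (!nrow(pairs)) return(FALSE)
        if (!any(.edgeKey(pairs[[1]], pairs[[2]]) %in% bbKeys[[spO]]))
          return(FALSE)
      }
      TRUE
    }, logical(1))
    kept <- tab[keep, , drop = FALSE]
    rownames(kept) <- NULL
    edges[[sp]] <- kept
    nodes[[sp]] <- sort(unique(c(kept$gene_a, kept$gene_b)))
  }
  new("OrthoBackbone", edges = edges, nodes = nodes)
}

#' Jaccard similarity of two edge sets
#'
#' `|A intersect B| / |A union B|` over unordered node pairs. Both sets
#' must live in the same gene namespace. Two empty sets give 0 with a
#' warning.
#'
#' @param edgesA,edgesB data.frames with columns `gene_a`, `gene_b` (or
#'   two-column matrices).
#' @return a number in `[0, 1]`.
#' @export
edgeJaccard <- function(edgesA, edgesB) {
  keyOf <- function(e) {
    e <- as.data.frame(e, stringsAsFactors = FALSE)
    if (!nrow(e)) return(character())
    unique(.edgeKey(as.character(e[[1]]), as.character(e[[2]])))
  }
  a <- keyOf(edgesA); b <- keyOf(edgesB)
  u <- length(union(a, b))
  if (u == 0) {
    warning("both edge sets empty; Jaccard defined as 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Select core edges by annotation membership
#'
#' Keeps edges with at least one endpoint in the intersection of two
#' annotation sets (e.g. spermatogenesis-related genes that are also
#' expression regulators). `mode = "each-set"` instead requires one
#' endpoint in each set.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`.
#' @param setX,setY character vectors of gene ids.
#' @param mode `"intersection"` (default) or `"each-set"`.
#' @return the selected subset of `edges`.
#' @export
selectCore <- function(edges, setX, setY,
                       mode = c("intersection", "each-set")) {
  mode <- match.arg(mode)
  keep <- if (mode == "intersection") {
    core <- intersect(setX, setY)
    edges$gene_a %in% core | edges$gene_b %in% core
  } else {
    (edges$gene_a %in% setX & edges$gene_b %in% setY) |
      (edges$gene_a %in% setY & edges$gene_b %in% setX)
  }
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Edge disruption by a differentially expressed gene set
#'
#' Counts the edges with at least one endpoint in `deg` and reports the
#' disrupted fraction. The edge set must be non-empty.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` (e.g. one
#'   layer of [obEdges()]).
#' @param deg character vector of differentially expressed genes.
#' @return list with `total`, `disrupted`, `fraction`.
#' @export
edgeDisruption <- function(edges, deg) {
  if (is.null(edges) || nrow(edges) == 0)
    stop("edge set is empty; disruption fraction undefined")
  hit <- edges$gene_a %in% deg | edges$gene_b %in% deg
  list(total = nrow(edges), disrupted = sum(hit),
       fraction = sum(hit) / nrow(edges))
}

#' Compare two disruption fractions
#'
#' Two-sided Fisher's exact test on the 2x2 table of disrupted vs intact
#' edges of two edge sets.
#'
#' @param reportA,reportB results of [edgeDisruption()].
#' @return an `htest` from [stats::fisher.test()].
#' @export
disruptionTest <- function(reportA, reportB) {
  tab <- matrix(c(reportA$disrupted, reportA$total - reportA$disrupted,
                  reportB$disrupted, reportB$total - reportB$disrupted),
                nrow = 2)
  fisher.test(tab, alternative = "two.sided")
}
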