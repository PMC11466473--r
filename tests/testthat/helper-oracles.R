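# Independent oracles and small generators used across the suite. These
# deliberately avoid the package's own code paths: Floyd-Warshall instead
# of Dijkstra, a clade-scan instead of getMRCA, and a direct enumeration
# of ortholog pairs instead of the link-map machinery.

# random weighted layer: G(n, p) with uniform scores in [0.05, 1]
randomLayer <- function(n, p, seed, species = "toy") {
  set.seed(seed)
  pairs <- t(combn(paste0("n", sprintf("%02d", seq_len(n))), 2))
  sel <- runif(nrow(pairs)) < p
  edges <- data.frame(gene_a = pairs[sel, 1], gene_b = pairs[sel, 2],
                      score = runif(sum(sel), 0.05, 1),
                      stringsAsFactors = FALSE)
  buildLayer(edges, unique(c(pairs)), minScore = 0, species = species,
             keepIsolated = TRUE)
}

# Floyd-Warshall metric/semi-metric classification of a layer's edges
fwClassify <- function(layer, relTol = 1e-9) {
  g <- layerGraph(layer)
  n <- igraph::vcount(g)
  tab <- edgeTable(layer)
  nm <- igraph::V(g)$name
  D <- matrix(Inf, n, n, dimnames = list(nm, nm))
  diag(D) <- 0
  for (i in seq_len(nrow(tab))) {
    a <- tab$gene_a[i]; b <- tab$gene_b[i]
    D[a, b] <- D[b, a] <- min(D[a, b], tab$distance[i])
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  vapply(seq_len(nrow(tab)), function(i)
    D[tab$gene_a[i], tab$gene_b[i]] >= tab$distance[i] / (1 + relTol),
    logical(1))
}

# deepest ranked node whose clade contains every member species
scanRank <- function(rt, speciesSet) {
  tr <- slot(rt, "tree")
  ntip <- length(tr$tip.label)
  clades <- lapply(slot(rt, "pathNodes"), function(nd) {
    if (nd <= ntip) tr$tip.label[nd]
    else ape::extract.clade(tr, nd)$tip.label
  })
  best <- NA_integer_
  for (i in seq_along(clades))
    if (all(speciesSet %in% clades[[i]])) best <- i
  best
}

# brute-force orthoBackbone: enumerate, per backbone edge, every ortholog
# pair in every other layer straight from the orthogroup table
bruteOrthoBackbone <- function(og, layers, backbones) {
  species <- names(layers)
  bbTab <- lapply(species, function(sp) {
    g <- backboneGraph(backbones[[sp]])
    if (igraph::ecount(g) == 0) return(matrix(character(), ncol = 2))
    igraph::as_edgelist(g, names = TRUE)
  })
  names(bbTab) <- species
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  bbKeys <- lapply(bbTab, function(m)
    if (nrow(m)) key(m[, 1], m[, 2]) else character())
  orthologsOf <- function(gene, spFrom, spTo) {
    ogs <- og$orthogroup[og$species == spFrom & og$gene == gene]
    if (!length(ogs)) return(character())
    cand <- og$gene[og$species == spTo & og$orthogroup %in% ogs]
    intersect(cand, igraph::V(layerGraph(layers[[spTo]]))$name)
  }
  out <- list()
  for (sp in species) {
    m <- bbTab[[sp]]
    keep <- logical(nrow(m))
    for (i in seq_len(nrow(m))) {
      ok <- TRUE
      for (spO in setdiff(species, sp)) {
        found <- FALSE
        for (a2 in orthologsOf(m[i, 1], sp, spO))
          for (b2 in orthologsOf(m[i, 2], sp, spO))
            if (a2 != b2 && key(a2, b2) %in% bbKeys[[spO]]) found <- TRUE
        if (!found) { ok <- FALSE; break }
      }
      keep[i] <- ok
    }
    kept <- m[keep, , drop = FALSE]
    out[[sp]] <- if (nrow(kept)) sort(key(kept[, 1], kept[, 2]))
                 else character()
  }
  out
}

# canonical sorted edge keys of one orthoBackbone layer, for comparisons
obKeys <- function(ob, sp) {
  e <- obEdges(ob, sp)
  if (!nrow(e)) return(character())
  sort(paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b)))
}

# build a Layer directly from an edge data.frame (gene_a, gene_b, score)
toyLayer <- function(edges, species = "toy", genes = NULL) {
  if (is.null(genes)) genes <- unique(c(edges$gene_a, edges$gene_b))
  buildLayer(edges, genes, minScore = 0, species = species,
             keepIsolated = TRUE)
}

# tiny SummarizedExperiment from a matrix and sample->group map
toySE <- function(mat, groups) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = mat),
    colData = S4Vectors::DataFrame(group = unname(groups[colnames(mat)]),
                                   row.names = colnames(mat)))
}

# random rooted binary tree over nLeaves labelled species
randomTree <- function(nLeaves, seed) {
  set.seed(seed)
  ape::rtree(nLeaves, rooted = TRUE,
             tip.label = paste0("sp", sample(seq_len(nLeaves))))
}
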