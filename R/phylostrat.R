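# Phylostratigraphy: rank the root-to-focal path of a rooted species tree
# into phylostrata, assign orthogroups (hence focal-species genes) to the
# oldest clade containing all their member species, and compute
# transcriptome age statistics from TPM expression.

#' Rank a species tree into phylostrata
#'
#' Numbers the nodes on the root-to-focal-species path 1..K in root-to-leaf
#' order: rank 1 is the root (oldest clade), rank K the focal leaf
#' (species-specific). Multifurcations along the path are allowed; each
#' node still receives one rank. The tree must be rooted with a bifurcating
#' root.
#'
#' @param tree a rooted tree: an `ape::phylo` object, a Newick string, or a
#'   path to a Newick file.
#' @param focal focal species; must be a leaf label.
#' @return a [RankedSpeciesTree-class].
#' @examples
#' rt <- rankTree("((A,B),C);", "A")
#' strataRanks(rt)   # root = 1, (A,B) clade = 2, A = 3
#' @export
rankTree <- function(tree, focal) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("cannot parse tree: expected Newick input or a phylo object")
  if (!ape::is.rooted(tree))
    stop("tree must be rooted (binary root); unrooted or ",
         "multifurcating-at-root input is not supported")
  if (length(focal) != 1L || !focal %in% tree$tip.label)
    stop("focal species '", focal, "' is not a leaf of the tree")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  tip <- match(focal, tree$tip.label)
  path <- as.integer(ape::nodepath(tree, from = root, to = tip))
  new("RankedSpeciesTree", tree = tree, focal = focal,
      pathNodes = path, K = length(path))
}

#' Assign focal-species genes to phylostrata
#'
#' Each orthogroup containing at least one focal-species gene is assigned
#' to the oldest clade spanned by its member species — the most recent
#' common ancestor of all species with members, which necessarily lies on
#' the ranked root-to-focal path. All focal genes of the orthogroup inherit
#' that rank. Focal genes present in no orthogroup (orphans) and
#' focal-only orthogroups receive rank K (species-specific), the
#' phylostratigraphy convention for lineage-restricted genes.
#'
#' @param og long-format orthogroup table (`orthogroup`, `species`,
#'   `gene`), as from [readOrthogroups()].
#' @param rt a [RankedSpeciesTree-class].
#' @param orphanGenes optional character vector of focal-species genes not
#'   present in `og`, to be assigned rank K.
#' @return named integer vector: gene id -> phylostratum rank in 1..K.
#' @export
assignPhylostrata <- function(og, rt, orphanGenes = NULL) {
  stopifnot(is(rt, "RankedSpeciesTree"))
  badSp <- setdiff(unique(og$species), rt@tree$tip.label)
  if (length(badSp))
    stop("species not in tree: ", paste(badSp, collapse = ", "))
  focal <- rt@focal
  keep <- og$orthogroup %in% unique(og$orthogroup[og$species == focal &
                                                  og$gene != ""])
  sub <- og[keep, , drop = FALSE]
  ranks <- integer(0)
  if (nrow(sub)) {
    tr <- rt@tree
    focalTip <- match(focal, tr$tip.label)
    spPerOg <- split(sub$species, sub$orthogroup)
    ogRank <- vapply(spPerOg, function(spp) {
      spp <- unique(spp)
      node <- if (length(spp) == 1L) focalTip
              else ape::getMRCA(tr, spp)
      r <- match(node, rt@pathNodes)
      if (is.na(r))
        stop("orthogroup ancestor off the ranked path; is the focal ",
             "species a member?")
      r
    }, integer(1))
    focalRows <- sub[sub$species == focal, , drop = FALSE]
    ranks <- setNames(ogRank[focalRows$orthogroup], focalRows$gene)
  }
  if (!is.null(orphanGenes)) {
    orphans <- setdiff(orphanGenes, names(ranks))
    ranks <- c(ranks, setNames(rep(rt@K, length(orphans)), orphans))
  }
  storage.mode(ranks) <- "integer"
  ranks
}

.meanTpm <- function(se, samples = NULL) {
  mat <- SummarizedExperiment::assay(se, "tpm")
  if (!is.null(samples)) mat <- mat[, samples, drop = FALSE]
  rowMeans(mat)
}

#' Transcriptome age index
#'
#' The TAI of a sample is the expression-weighted mean phylostratum rank of
#' its expressed genes: `sum(rank_i * TPM_i) / sum(TPM_i)` over genes with
#' mean TPM above `cutoff`. Higher values indicate younger transcriptomes.
#' The index is invariant under positive rescaling of expression and
#' bounded by the youngest and oldest contributing ranks.
#'
#' @param se `SummarizedExperiment` with a `tpm` assay and `group` column
#'   data, as from [readExpression()].
#' @param ps named integer vector gene -> rank, as from
#'   [assignPhylostrata()]; genes without a rank are ignored.
#' @param cutoff expression cutoff: genes with mean TPM (across the
#'   considered samples) at or below it are excluded. Defaults to 1,
#'   the "minimum average TPM > 1" convention; set to 0 to include every
#'   gene with nonzero expression, as classic TAI does.
#' @param by `"sample"` filters genes on the mean over all samples and
#'   reports per-sample TAI plus per-group means; `"group"` filters and
#'   computes on per-group mean TPM.
#' @return list with `samples` (data.frame `sample`, `group`, `tai`),
#'   `groups` (data.frame `group`, `tai`), and `contributions` (matrix
#'   rank x sample — or rank x group for `by = "group"` — of shares of the
#'   TAI numerator, each column summing to 1).
#' @export
tai <- function(se, ps, cutoff = 1, by = c("sample", "group")) {
  by <- match.arg(by)
  mat <- SummarizedExperiment::assay(se, "tpm")
  groups <- as.character(SummarizedExperiment::colData(se)$group)
  common <- intersect(rownames(mat), names(ps))
  mat <- mat[common, , drop = FALSE]
  ranks <- ps[common]
  if (by == "group") {
    grpMeans <- vapply(unique(groups), function(g)
      rowMeans(mat[, groups == g, drop = FALSE]), numeric(nrow(mat)))
    mat <- matrix(grpMeans, nrow = nrow(mat),
                  dimnames = list(common, unique(groups)))
    groups <- unique(groups)
  }
  keep <- rowMeans(mat) > cutoff
  if (!any(keep)) stop("empty transcriptome: no gene passes the cutoff")
  mat <- mat[keep, , drop = FALSE]
  ranks <- ranks[keep]
  num <- colSums(mat * ranks)
  den <- colSums(mat)
  taiVals <- num / den
  allRanks <- sort(unique(ranks))
  contrib <- vapply(seq_len(ncol(mat)), function(j) {
    byRank <- vapply(allRanks, function(r)
      sum(mat[ranks == r, j] * r), numeric(1))
    byRank / sum(byRank)
  }, numeric(length(allRanks)))
  contrib <- matrix(contrib, nrow = length(allRanks),
                    dimnames = list(allRanks, colnames(mat)))
  samplesDf <- data.frame(sample = colnames(mat), group = groups,
                          tai = unname(taiVals), stringsAsFactors = FALSE)
  groupsDf <- data.frame(
    group = unique(groups),
    tai = vapply(unique(groups), function(g)
      mean(taiVals[groups == g]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(samples = samplesDf, groups = groupsDf, contributions = contrib)
}

#' Fraction of expressed genes in old phylostrata
#'
#' Per group, the fraction of expressed genes (mean TPM above `cutoff`
#' within the group) whose phylostratum rank falls in `oldRanks` —
#' by default strata 1..5, the metazoan-wide strata. Optionally compares
#' two groups' per-sample fractions with a two-sided Mann-Whitney U test.
#'
#' @inheritParams tai
#' @param oldRanks integer set of ranks counted as "old"; default `1:5`.
#' @param compare optional character vector of two group labels; adds a
#'   two-sided Mann-Whitney U test on per-sample fractions (each sample's
#'   fraction computed from genes with TPM above `cutoff` in that sample).
#' @return list with `fractions` (data.frame `group`, `n_expressed`,
#'   `fraction`) and, when `compare` is given, `test` (the `htest`).
#' @export
conservedFraction <- function(se, ps, oldRanks = 1:5, cutoff = 1,
                              compare = NULL) {
  mat <- SummarizedExperiment::assay(se, "tpm")
  groups <- as.character(SummarizedExperiment::colData(se)$group)
  common <- intersect(rownames(mat), names(ps))
  mat <- mat[common, , drop = FALSE]
  ranks <- ps[common]
  perGroup <- lapply(unique(groups), function(g) {
    m <- rowMeans(mat[, groups == g, drop = FALSE])
    expressed <- m > cutoff
    n <- sum(expressed)
    frac <- if (n) sum(ranks[expressed] %in% oldRanks) / n else 0
    data.frame(group = g, n_expressed = n, fraction = frac,
               stringsAsFactors = FALSE)
  })
  out <- list(fractions = do.call(rbind, perGroup))
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2, all(compare %in% groups))
    perSample <- function(g) {
      idx <- which(groups == g)
      vapply(idx, function(j) {
        expressed <- mat[, j] > cutoff
        if (!any(expressed)) return(0)
        sum(ranks[expressed] %in% oldRanks) / sum(expressed)
      }, numeric(1))
    }
    out$test <- wilcox.test(perSample(compare[1]), perSample(compare[2]),
                            alternative = "two.sided", exact = FALSE)
  }
  out
}

#' @rdname assignPhylostrata
#' @param ps named rank vector to serialize.
#' @param path output TSV path.
#' @export
writePhylostrata <- function(ps, path) {
  .writeTsv(data.frame(gene = names(ps), rank = unname(ps),
                       stringsAsFactors = FALSE), path)
}
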