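# Seeded synthetic multilayer generator with planted ground truth. The
# generator emulates the statistical structure the pipeline assumes: a
# conserved core present in every species layer (with paralogs), elevated
# core connectivity via a Chung-Lu expected-degree model, Beta-distributed
# edge confidence scores, partially shared orthogroups that populate
# intermediate phylostrata, a planted age-by-stage expression trend, and
# biased DEG sets. One global seed drives derived per-component seeds so
# any stage is reproducible in isolation.

.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483646) + 1L
}

#' Configuration for the synthetic multilayer generator
#'
#' Validated parameter bundle for [simulateMultilayer()],
#' [simulateExpression()] and [simulateDeg()].
#'
#' @param nLayers number of species layers (default 3, mirroring a
#'   three-species comparison).
#' @param genesPerLayer genes per layer (default 2000, a desk-scale stand-in
#'   for the roughly 8000-11000-gene cell-type networks the method targets).
#' @param conservedFraction fraction of each layer's genes in orthogroups
#'   spanning all layers (default 0.5; deeply conserved genes make up
#'   roughly half of such networks).
#' @param degreeMultiplier mean-degree ratio of the conserved core to the
#'   background (default 3; conserved genes are markedly more connected).
#' @param paralogRate probability that a conserved orthogroup has two
#'   copies in a layer (default 0.3).
#' @param meanDegree background mean degree (default 10).
#' @param interologRate fraction of a conserved gene's elevated expected
#'   degree realized as interologs — core interactions planted between the
#'   same orthogroups in every layer (default 0.3). At 0 the layers are
#'   wired independently and cross-species edge conservation arises only
#'   by chance, which is not how conserved interactomes behave.
#' @param scoreShape Beta(shape1, shape2) parameters for edge confidence
#'   scores, truncated to (0, 1] (default c(4, 2): right-skewed, most
#'   scores above the 0.5 confidence filter).
#' @param partialFraction fraction of genes in orthogroups shared by a
#'   proper prefix of the species (populates intermediate phylostrata;
#'   default 0.1, ignored when `nLayers < 3`).
#' @param stageAgeSlope per-stage log-expression trend coefficient applied
#'   proportionally to a gene's centered phylostratum rank, so positive
#'   values make later stages younger (default 0.5).
#' @param stages ordered developmental stage labels for expression.
#' @param replicates samples per stage (default 3).
#' @param degFraction fraction of genes sampled as DEGs (default 0.1).
#' @param seed global integer seed.
#' @return a validated `list` of class `SimulationConfig`.
#' @export
simulationConfig <- function(nLayers = 3, genesPerLayer = 2000,
                             conservedFraction = 0.5, degreeMultiplier = 3,
                             paralogRate = 0.3, meanDegree = 10,
                             interologRate = 0.3,
                             scoreShape = c(4, 2), partialFraction = 0.1,
                             stageAgeSlope = 0.5,
                             stages = c("spermatogonia", "spermatocyte",
                                        "spermatid"),
                             replicates = 3, degFraction = 0.1, seed = 1) {
  stopifnot(nLayers >= 2, genesPerLayer >= 10,
            conservedFraction > 0, conservedFraction <= 1,
            degreeMultiplier >= 1, paralogRate >= 0, paralogRate <= 1,
            meanDegree > 0, interologRate >= 0, interologRate <= 1,
            length(scoreShape) == 2, all(scoreShape > 0),
            partialFraction >= 0, partialFraction < 1,
            replicates >= 1, degFraction >= 0, degFraction <= 1)
  if (degreeMultiplier * meanDegree >= genesPerLayer - 1)
    stop("infeasible degree demand: mean degree must be below n - 1")
  structure(list(nLayers = nLayers, genesPerLayer = genesPerLayer,
                 conservedFraction = conservedFraction,
                 degreeMultiplier = degreeMultiplier,
                 paralogRate = paralogRate, meanDegree = meanDegree,
                 interologRate = interologRate,
                 scoreShape = scoreShape, partialFraction = partialFraction,
                 stageAgeSlope = stageAgeSlope, stages = stages,
                 replicates = replicates, degFraction = degFraction,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# caterpillar tree over sp1..spL with sp1 focal:
# ((..((sp1,sp2),sp3)..,spL); ranked path has K = L strata
.simTree <- function(nLayers) {
  txt <- "(sp1,sp2)"
  if (nLayers > 2)
    for (l in 3:nLayers) txt <- sprintf("(%s,sp%d)", txt, l)
  paste0(txt, ";")
}

# Chung-Lu expected-degree graph on weights w; returns 2-col index matrix
.chungLu <- function(w) {
  n <- length(w)
  s <- sum(w)
  iu <- which(upper.tri(matrix(FALSE, n, n)))
  i <- ((iu - 1L) %% n) + 1L
  j <- ((iu - 1L) %/% n) + 1L
  p <- pmin(w[i] * w[j] / s, 1)
  sel <- runif(length(p)) < p
  cbind(i[sel], j[sel])
}

#' Simulate a multilayer network with planted ground truth
#'
#' Generates `nLayers` species layers in which conserved orthogroups span
#' every layer (with two copies per layer at `paralogRate`), partial
#' orthogroups span a prefix of the species (so the focal species'
#' phylostrata 2..K-1 are populated), and the remaining genes are
#' species-specific — half of them in singleton orthogroups, half orphans
#' absent from the table. Each layer is a Chung-Lu expected-degree graph
#' where conserved genes (and their paralogs) get `degreeMultiplier` times
#' the background expected degree; edge scores are Beta-distributed,
#' truncated to (0, 1]. The output is deterministic given `cfg$seed`.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `layers` (named list of [Layer-class]), `orthogroups`
#'   (long-format table), `tree` (Newick string, focal species `sp1`), and
#'   `truth` (list: `genes` data.frame with `species`, `gene`,
#'   `orthogroup`, `conserved`, `rank`; `focal`; `config`).
#' @export
simulateMultilayer <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(.childSeed(cfg$seed, 1))
  L <- cfg$nLayers
  species <- paste0("sp", seq_len(L))
  K <- L  # ranked path length of the caterpillar tree
  nCons <- round(cfg$conservedFraction * cfg$genesPerLayer)
  prefixes <- if (L >= 3) 2:(L - 1) else integer(0)
  nPartialPer <- if (length(prefixes))
    round(cfg$partialFraction * cfg$genesPerLayer / length(prefixes))
  else 0

  chunks <- list()
  # conserved orthogroups: members (1 or 2 copies) in every layer; these
  # map to the root -> rank 1
  paralog <- matrix(runif(nCons * L) < cfg$paralogRate, nCons, L)
  for (l in seq_len(L)) {
    sp <- species[l]
    g1 <- sprintf("%s_c%05d", sp, seq_len(nCons))
    ogc <- sprintf("OGC%05d", seq_len(nCons))
    par <- which(paralog[, l])
    parGenes <- if (length(par)) paste0(g1[par], "b") else character()
    chunks[[length(chunks) + 1L]] <- data.frame(
      species = sp, gene = c(g1, parGenes),
      orthogroup = c(ogc, ogc[par]), conserved = TRUE, rank = 1L,
      wMult = cfg$degreeMultiplier, stringsAsFactors = FALSE)
  }
  # partial orthogroups over species 1..j (j < L): MRCA is the clade of
  # that prefix, i.e. rank K - j + 1 on the caterpillar
  for (j in prefixes) {
    if (nPartialPer == 0) next
    for (l in seq_len(j)) {
      sp <- species[l]
      chunks[[length(chunks) + 1L]] <- data.frame(
        species = sp,
        gene = sprintf("%s_p%d_%05d", sp, j, seq_len(nPartialPer)),
        orthogroup = sprintf("OGP%d_%05d", j, seq_len(nPartialPer)),
        conserved = FALSE, rank = as.integer(K - j + 1), wMult = 1,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, chunks)
  # species-specific genes fill each layer to genesPerLayer; half get a
  # singleton orthogroup, half are orphans (rank K either way)
  for (l in seq_len(L)) {
    sp <- species[l]
    nSoFar <- sum(truth$species == sp)
    nSpec <- max(cfg$genesPerLayer - nSoFar, 0)
    if (nSpec == 0) next
    idx <- seq_len(nSpec)
    truth <- rbind(truth, data.frame(
      species = sp, gene = sprintf("%s_s%05d", sp, idx),
      orthogroup = ifelse(idx %% 2 == 0,
                          sprintf("OGS_%s_%05d", sp, idx), NA_character_),
      conserved = FALSE, rank = as.integer(K), wMult = 1,
      stringsAsFactors = FALSE))
  }
  og <- truth[!is.na(truth$orthogroup),
              c("orthogroup", "species", "gene"), drop = FALSE]
  perLayerGenes <- split(truth$gene, truth$species)[species]
  perLayerCons <- split(truth$conserved, truth$species)[species]
  truth <- truth[, c("species", "gene", "orthogroup", "conserved", "rank")]
  rownames(og) <- rownames(truth) <- NULL

  # interolog core: one edge set over conserved orthogroups, planted
  # between the primary copies in every layer, supplying interologRate of
  # a conserved gene's elevated expected degree; the remainder (and all
  # background wiring) is drawn independently per layer
  coreDeg <- cfg$interologRate * cfg$degreeMultiplier * cfg$meanDegree
  coreEdges <- matrix(integer(), ncol = 2)
  if (nCons >= 2 && coreDeg > 0) {
    set.seed(.childSeed(cfg$seed, 50))
    pc <- min(coreDeg / (nCons - 1), 1)
    iu <- which(upper.tri(matrix(FALSE, nCons, nCons)))
    ci <- ((iu - 1L) %% nCons) + 1L
    cj <- ((iu - 1L) %/% nCons) + 1L
    selc <- runif(length(iu)) < pc
    coreEdges <- cbind(ci[selc], cj[selc])
  }

  layers <- setNames(vector("list", L), species)
  for (l in seq_len(L)) {
    set.seed(.childSeed(cfg$seed, 100 + l))
    genes <- perLayerGenes[[species[l]]]
    w <- ifelse(perLayerCons[[species[l]]],
                cfg$degreeMultiplier * cfg$meanDegree, cfg$meanDegree)
    primary <- match(sprintf("%s_c%05d", species[l], seq_len(nCons)),
                     genes)
    # primary copies get coreDeg of their degree from the planted core;
    # paralog copies are wired independently at the full rate
    if (nrow(coreEdges))
      w[primary] <- pmax(w[primary] - coreDeg, 0.1)
    el <- .chungLu(w)
    if (nrow(coreEdges)) {
      el <- rbind(cbind(primary[coreEdges[, 1]],
                        primary[coreEdges[, 2]]), el)
      el <- el[!duplicated(paste(pmin(el[, 1], el[, 2]),
                                 pmax(el[, 1], el[, 2]))), ,
               drop = FALSE]
    }
    scores <- rbeta(nrow(el), cfg$scoreShape[1], cfg$scoreShape[2])
    scores <- pmin(pmax(scores, 1e-6), 1)
    g <- igraph::graph_from_data_frame(
      data.frame(from = genes[el[, 1]], to = genes[el[, 2]],
                 stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = genes, stringsAsFactors = FALSE))
    g <- igraph::set_edge_attr(g, "score", value = scores)
    g <- igraph::set_edge_attr(g, "distance", value = toDistance(scores))
    cons <- truth$conserved[truth$species == species[l]][
      match(genes, truth$gene[truth$species == species[l]])]
    g <- igraph::set_vertex_attr(g, "conserved", value = cons)
    layers[[species[l]]] <- .layerFromGraph(g, species[l])
  }
  list(layers = layers, orthogroups = og, tree = .simTree(L),
       truth = list(genes = truth, focal = species[1], config = cfg))
}

#' Simulate a staged expression matrix with a planted age trend
#'
#' Log-normal TPM for the focal species' genes across ordered stages with
#' `replicates` samples each. The log-mean of each gene shifts by
#' `stageAgeSlope * (stage - 1) * (rank - meanRank) / K`, so with a
#' positive slope the expression share of young (high-rank) genes grows
#' stage by stage and the planted transcriptome age index increases.
#'
#' @param truth the `truth` element of [simulateMultilayer()] output.
#' @param stages ordered stage labels; defaults to `cfg$stages`.
#' @param cfg the [simulationConfig()]; defaults to `truth$config`.
#' @param seed integer seed; defaults to a child of `cfg$seed`.
#' @return list with `se` (a `SummarizedExperiment`, assay `tpm`, column
#'   data `group`) and `groupMap` (sample -> stage).
#' @export
simulateExpression <- function(truth, stages = NULL, cfg = NULL,
                               seed = NULL) {
  if (is.null(cfg)) cfg <- truth$config
  if (is.null(stages)) stages <- cfg$stages
  if (is.null(seed)) seed <- .childSeed(cfg$seed, 2)
  set.seed(seed)
  genes <- truth$genes[truth$genes$species == truth$focal, , drop = FALSE]
  K <- max(genes$rank)
  z <- (genes$rank - mean(genes$rank)) / K
  nStage <- length(stages)
  samples <- paste0(rep(stages, each = cfg$replicates), "_r",
                    rep(seq_len(cfg$replicates), nStage))
  groupMap <- setNames(rep(stages, each = cfg$replicates), samples)
  mat <- matrix(0, nrow = nrow(genes), ncol = length(samples),
                dimnames = list(genes$gene, samples))
  base <- rlnorm(nrow(genes), meanlog = 1, sdlog = 1)
  for (s in seq_len(nStage)) {
    shift <- exp(cfg$stageAgeSlope * (s - 1) * z)
    for (r in seq_len(cfg$replicates)) {
      col <- (s - 1) * cfg$replicates + r
      noise <- rlnorm(nrow(genes), meanlog = 0, sdlog = 0.3)
      mat[, col] <- base * shift * noise
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = mat),
    colData = S4Vectors::DataFrame(group = unname(groupMap[samples]),
                                   row.names = samples))
  list(se = se, groupMap = groupMap)
}

#' Simulate a differentially-expressed gene set
#'
#' Samples `degFraction` of one species' genes without replacement;
#' `biasToCore > 1` oversamples conserved genes with that odds weight.
#' Deterministic given `seed`.
#'
#' @param truth the `truth` element of [simulateMultilayer()] output.
#' @param degFraction fraction of genes to sample; defaults to
#'   `truth$config$degFraction`.
#' @param biasToCore odds weight of conserved genes relative to background
#'   (default 1, unbiased).
#' @param seed integer seed; defaults to a child of the config seed.
#' @param species species whose genes are sampled; defaults to the focal.
#' @return character vector of gene ids with a `label` attribute.
#' @export
simulateDeg <- function(truth, degFraction = NULL, biasToCore = 1,
                        seed = NULL, species = NULL) {
  cfg <- truth$config
  if (is.null(degFraction)) degFraction <- cfg$degFraction
  if (is.null(seed)) seed <- .childSeed(cfg$seed, 3)
  if (is.null(species)) species <- truth$focal
  genes <- truth$genes[truth$genes$species == species, , drop = FALSE]
  n <- round(degFraction * nrow(genes))
  if (n == 0) return(structure(character(), label = "deg"))
  set.seed(seed)
  w <- ifelse(genes$conserved, biasToCore, 1)
  structure(sort(sample(genes$gene, n, prob = w)), label = "deg")
}
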