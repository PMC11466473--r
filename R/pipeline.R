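# Pipeline subcommands: thin, file-oriented wrappers around the package
# functions, each writing fixed-name outputs plus a machine-readable run
# manifest (inputs with checksums, parameters, seed, version) so any run
# can be reproduced exactly. The `obkit` script under inst/scripts/ is a
# shell entry point over runSubcommand().

.manifest <- function(outDir, subcommand, inputs, params, seed) {
  inputInfo <- lapply(inputs, function(p) {
    if (is.character(p) && length(p) == 1 && file.exists(p))
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    else p
  })
  man <- list(tool = "obkit",
              version = as.character(packageVersion("obkit")),
              subcommand = subcommand, inputs = inputInfo,
              parameters = params, seed = seed)
  jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(man)
}

# read a layer TSV (gene_a, gene_b, score, distance) [+ node TSV] back
.readLayerTsv <- function(edgePath, nodePath = NULL, species = "species") {
  tab <- read.table(edgePath, header = TRUE, sep = "\t",
                    comment.char = "#", stringsAsFactors = FALSE)
  verts <- unique(c(tab$gene_a, tab$gene_b))
  cons <- NULL
  if (!is.null(nodePath) && file.exists(nodePath)) {
    nodes <- read.table(nodePath, header = TRUE, sep = "\t",
                        comment.char = "#", stringsAsFactors = FALSE)
    verts <- unique(c(verts, nodes$gene))
    cons <- setNames(as.logical(nodes$conserved), nodes$gene)
  }
  g <- igraph::graph_from_data_frame(
    tab[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  g <- igraph::set_edge_attr(g, "score", value = tab$score)
  g <- igraph::set_edge_attr(g, "distance", value = tab$distance)
  if (!is.null(cons))
    g <- igraph::set_vertex_attr(g, "conserved",
                                 value = unname(cons[igraph::V(g)$name]))
  .layerFromGraph(g, species)
}

.cfgGet <- function(config, name, default = NULL) {
  if (!is.null(config[[name]])) config[[name]] else default
}

#' Run one pipeline subcommand
#'
#' File-level interface to the pipeline. Each subcommand reads the paths
#' named in `config`, runs the corresponding package functions with the
#' documented defaults (`tpm_cutoff = 1`, `min_score = 0.5`,
#' `old_ranks = 1:5`), writes fixed-name outputs under `outDir`, and
#' writes `manifest.json` describing inputs (with checksums), parameters
#' and seed. Outputs carry no timestamps, so a rerun with identical inputs
#' is byte-identical.
#'
#' Subcommands and their main outputs:
#' \describe{
#'   \item{simulate}{synthetic multilayer inputs: `edges_<sp>.tsv`,
#'     `genes_<sp>.tsv`, `expression.tsv`, `groups.tsv`,
#'     `orthogroups.tsv`, `tree.nwk`, `deg.tsv`, `truth.json`.}
#'   \item{phylostrata}{`phylostrata.tsv` (gene, rank).}
#'   \item{tai}{`tai.tsv` (per sample) and `tai_groups.tsv`.}
#'   \item{build}{per species `layer_<sp>.tsv` + `nodes_<sp>.tsv`.}
#'   \item{backbone}{per species `backbone_<sp>.tsv` (edge table with a
#'     `metric` column).}
#'   \item{orthobackbone}{per species `orthobackbone_<sp>.tsv` plus
#'     `links.tsv`.}
#'   \item{features}{per species `features_<sp>.tsv`.}
#'   \item{classify}{`classifier_report.json`.}
#'   \item{rewire}{per species `rewired_<sp>.tsv`.}
#'   \item{disrupt}{`disruption.json`.}
#' }
#'
#' @param name subcommand name (see Details).
#' @param config named list of paths and parameters; see the package
#'   vignette for the full schema. For multi-species subcommands,
#'   `config$species` is a named list mapping species id to its file
#'   paths (`edges`, `genes`, `layer`, `nodes`, ...).
#' @param outDir output directory (created if missing).
#' @param seed integer seed for stochastic subcommands; overrides
#'   `config$seed`.
#' @return invisibly, a list of the main in-memory results.
#' @export
runSubcommand <- function(name, config = list(), outDir = ".",
                          seed = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(seed)) seed <- .cfgGet(config, "seed", 1L)
  seed <- as.integer(seed)
  switch(name,
    simulate = .cmdSimulate(config, outDir, seed),
    phylostrata = .cmdPhylostrata(config, outDir),
    tai = .cmdTai(config, outDir),
    build = .cmdBuild(config, outDir),
    backbone = .cmdBackbone(config, outDir),
    orthobackbone = .cmdOrthoBackbone(config, outDir),
    features = .cmdFeatures(config, outDir),
    classify = .cmdClassify(config, outDir, seed),
    rewire = .cmdRewire(config, outDir, seed),
    disrupt = .cmdDisrupt(config, outDir),
    stop("unknown subcommand '", name, "'")
  )
}

.cmdSimulate <- function(config, outDir, seed) {
  simArgs <- .cfgGet(config, "simulate", list())
  simArgs$seed <- seed
  cfg <- do.call(simulationConfig, simArgs)
  sim <- simulateMultilayer(cfg)
  expr <- simulateExpression(sim$truth)
  deg <- simulateDeg(sim$truth)
  for (sp in names(sim$layers)) {
    writeLayer(sim$layers[[sp]], file.path(outDir,
                                           sprintf("edges_%s.tsv", sp)))
    writeGeneSet(igraph::V(sim$layers[[sp]]@graph)$name,
                 file.path(outDir, sprintf("genes_%s.tsv", sp)))
  }
  writeExpression(expr$se, file.path(outDir, "expression.tsv"))
  .writeTsv(data.frame(sample = names(expr$groupMap),
                       group = unname(expr$groupMap),
                       stringsAsFactors = FALSE),
            file.path(outDir, "groups.tsv"))
  writeOrthogroups(sim$orthogroups, file.path(outDir, "orthogroups.tsv"))
  writeLines(sim$tree, file.path(outDir, "tree.nwk"))
  writeGeneSet(deg, file.path(outDir, "deg.tsv"))
  jsonlite::write_json(
    list(focal = sim$truth$focal,
         genes = sim$truth$genes,
         config = unclass(cfg)),
    file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA)
  .manifest(outDir, "simulate", list(), unclass(cfg), seed)
  invisible(sim)
}

.cmdPhylostrata <- function(config, outDir) {
  rt <- rankTree(config$tree, config$focal)
  og <- readOrthogroups(config$orthogroups)
  orphans <- if (!is.null(config$genes)) readGeneSet(config$genes) else NULL
  ps <- assignPhylostrata(og, rt, orphanGenes = orphans)
  writePhylostrata(ps, file.path(outDir, "phylostrata.tsv"))
  .manifest(outDir, "phylostrata",
            list(tree = config$tree, orthogroups = config$orthogroups,
                 genes = config$genes),
            list(focal = config$focal), NULL)
  invisible(ps)
}

.readGroupMap <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  setNames(as.character(tab$group), tab$sample)
}

.readPhylostrata <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  setNames(as.integer(tab$rank), tab$gene)
}

.cmdTai <- function(config, outDir) {
  se <- readExpression(config$expression, .readGroupMap(config$groups))
  ps <- .readPhylostrata(config$phylostrata)
  res <- tai(se, ps, cutoff = .cfgGet(config, "tpm_cutoff", 1))
  .writeTsv(res$samples, file.path(outDir, "tai.tsv"))
  .writeTsv(res$groups, file.path(outDir, "tai_groups.tsv"))
  .manifest(outDir, "tai",
            list(expression = config$expression, groups = config$groups,
                 phylostrata = config$phylostrata),
            list(tpm_cutoff = .cfgGet(config, "tpm_cutoff", 1)), NULL)
  invisible(res)
}

.cmdBuild <- function(config, outDir) {
  minScore <- .cfgGet(config, "min_score", 0.5)
  cutoff <- .cfgGet(config, "tpm_cutoff", 1)
  applyLcc <- .cfgGet(config, "lcc", TRUE)
  layers <- list()
  for (sp in names(config$species)) {
    spc <- config$species[[sp]]
    edges <- readEdges(spc$edges)
    genes <- if (!is.null(spc$expression)) {
      se <- readExpression(spc$expression, .readGroupMap(spc$groups))
      expressedGenes(se, spc$group, cutoff = cutoff)
    } else readGeneSet(spc$genes)
    layer <- buildLayer(edges, genes, minScore = minScore, species = sp)
    if (applyLcc) layer <- largestComponent(layer)
    writeLayer(layer, file.path(outDir, sprintf("layer_%s.tsv", sp)),
               file.path(outDir, sprintf("nodes_%s.tsv", sp)))
    layers[[sp]] <- layer
  }
  .manifest(outDir, "build",
            lapply(config$species, function(s) s$edges),
            list(min_score = minScore, tpm_cutoff = cutoff,
                 lcc = applyLcc), NULL)
  invisible(layers)
}

.layersFromConfig <- function(config) {
  layers <- list()
  for (sp in names(config$species)) {
    spc <- config$species[[sp]]
    layers[[sp]] <- .readLayerTsv(spc$layer, spc$nodes, species = sp)
  }
  layers
}

.cmdBackbone <- function(config, outDir) {
  layers <- .layersFromConfig(config)
  relTol <- .cfgGet(config, "rel_tol", 1e-9)
  bbs <- lapply(layers, metricBackbone, relTol = relTol)
  for (sp in names(bbs))
    writeLayer(bbs[[sp]], file.path(outDir,
                                    sprintf("backbone_%s.tsv", sp)))
  .manifest(outDir, "backbone",
            lapply(config$species, function(s) s$layer),
            list(rel_tol = relTol), NULL)
  invisible(bbs)
}

.cmdOrthoBackbone <- function(config, outDir) {
  layers <- .layersFromConfig(config)
  og <- readOrthogroups(config$orthogroups)
  ml <- linkLayers(og, layers)
  ml <- computeBackbones(ml, relTol = .cfgGet(config, "rel_tol", 1e-9))
  ob <- extractOrthoBackbone(ml)
  for (sp in names(obEdges(ob)))
    .writeTsv(obEdges(ob, sp),
              file.path(outDir, sprintf("orthobackbone_%s.tsv", sp)))
  .writeTsv(mlLinks(ml), file.path(outDir, "links.tsv"))
  .manifest(outDir, "orthobackbone",
            c(lapply(config$species, function(s) s$layer),
              list(orthogroups = config$orthogroups)),
            list(rel_tol = .cfgGet(config, "rel_tol", 1e-9)), NULL)
  invisible(ob)
}

.cmdFeatures <- function(config, outDir) {
  layers <- .layersFromConfig(config)
  # conservation labels come from orthogroup presence across all layers
  if (!is.null(config$orthogroups))
    layers <- mlLayers(linkLayers(readOrthogroups(config$orthogroups),
                                  layers))
  fts <- list()
  for (sp in names(layers)) {
    ft <- nodeFeatures(layers[[sp]],
                       damping = .cfgGet(config, "damping", 0.85))
    .writeTsv(ft, file.path(outDir, sprintf("features_%s.tsv", sp)))
    fts[[sp]] <- ft
  }
  .manifest(outDir, "features",
            c(lapply(config$species, function(s) s$layer),
              list(orthogroups = config$orthogroups)),
            list(damping = .cfgGet(config, "damping", 0.85)), NULL)
  invisible(fts)
}

.cmdClassify <- function(config, outDir, seed) {
  ft <- read.table(config$features, header = TRUE, sep = "\t",
                   comment.char = "#", stringsAsFactors = FALSE)
  model <- .cfgGet(config, "model", "random-forest")
  folds <- .cfgGet(config, "folds", 4)
  rep <- classifyConservation(ft, model = model, folds = folds,
                              seed = seed)
  rep$pr_curve <- rep$pr_curve[round(seq(1, nrow(rep$pr_curve),
                                         length.out = min(200, nrow(rep$pr_curve)))), ]
  jsonlite::write_json(rep, file.path(outDir, "classifier_report.json"),
                       auto_unbox = TRUE, digits = NA)
  .manifest(outDir, "classify", list(features = config$features),
            list(model = model, folds = folds), seed)
  invisible(rep)
}

.cmdRewire <- function(config, outDir, seed) {
  layers <- .layersFromConfig(config)
  fraction <- .cfgGet(config, "fraction", 0.5)
  out <- list()
  for (sp in names(layers)) {
    rw <- rewireLayer(layers[[sp]], fraction, seed)
    writeLayer(rw, file.path(outDir, sprintf("rewired_%s.tsv", sp)))
    out[[sp]] <- rw
  }
  .manifest(outDir, "rewire",
            lapply(config$species, function(s) s$layer),
            list(fraction = fraction), seed)
  invisible(out)
}

.cmdDisrupt <- function(config, outDir) {
  edges <- read.table(config$edges, header = TRUE, sep = "\t",
                      comment.char = "#", stringsAsFactors = FALSE)
  deg <- readGeneSet(config$deg)
  rep <- edgeDisruption(edges, deg)
  jsonlite::write_json(rep, file.path(outDir, "disruption.json"),
                       auto_unbox = TRUE, digits = NA)
  .manifest(outDir, "disrupt",
            list(edges = config$edges, deg = config$deg), list(), NULL)
  invisible(rep)
}

#' Load a YAML run configuration
#'
#' Reads a YAML configuration for [runSubcommand()]; values passed in
#' `overrides` (e.g. from command-line flags) win over file values.
#'
#' @param path YAML file (optional; `NULL` yields just the overrides).
#' @param overrides named list merged over the file contents.
#' @return a named list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  config <- if (!is.null(path)) yaml::read_yaml(path) else list()
  for (nm in names(overrides)) config[[nm]] <- overrides[[nm]]
  config
}
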