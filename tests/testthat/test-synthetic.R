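test_that("the generator is deterministic and respects its config", {
  cfg <- simulationConfig(nLayers = 3, genesPerLayer = 40, meanDegree = 5,
                          seed = 31)
  s1 <- simulateMultilayer(cfg)
  s2 <- simulateMultilayer(cfg)
  expect_identical(s1$orthogroups, s2$orthogroups)
  expect_identical(edgeTable(s1$layers$sp2), edgeTable(s2$layers$sp2))
  expect_identical(s1$truth$genes, s2$truth$genes)
  expect_equal(length(s1$layers), 3)
  for (sp in names(s1$layers))
    expect_equal(igraph::vcount(layerGraph(s1$layers[[sp]])), 40)
  expect_error(simulationConfig(genesPerLayer = 20, meanDegree = 25),
               "infeasible")
})

test_that("conserved genes span all layers; a full core links everything", {
  cfg <- simulationConfig(nLayers = 3, genesPerLayer = 30,
                          conservedFraction = 1, paralogRate = 0,
                          partialFraction = 0, meanDegree = 4, seed = 8)
  sim <- simulateMultilayer(cfg)
  ml <- linkLayers(sim$orthogroups, sim$layers)
  for (sp in names(sim$layers))
    expect_true(all(conservedNodes(mlLayers(ml)[[sp]])))
  # every orthogroup appears in every layer
  spPerOg <- tapply(sim$orthogroups$species, sim$orthogroups$orthogroup,
                    function(x) length(unique(x)))
  expect_true(all(spPerOg == 3))
})

test_that("degree multiplier 1 equalizes conserved and background degrees", {
  cfg <- simulationConfig(nLayers = 2, genesPerLayer = 2000,
                          degreeMultiplier = 1, meanDegree = 10,
                          partialFraction = 0, seed = 4)
  sim <- simulateMultilayer(cfg)
  g <- layerGraph(sim$layers$sp1)
  deg <- igraph::degree(g)
  cons <- conservedNodes(sim$layers$sp1)
  ratio <- mean(deg[cons]) / mean(deg[!cons])
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("planted interologs make the orthoBackbone non-trivial", {
  mk <- function(rate) {
    cfg <- simulationConfig(nLayers = 3, genesPerLayer = 300,
                            meanDegree = 8, interologRate = rate,
                            partialFraction = 0, seed = 55)
    sim <- simulateMultilayer(cfg)
    ob <- extractOrthoBackbone(computeBackbones(
      linkLayers(sim$orthogroups, sim$layers)))
    nrow(obEdges(ob, "sp1"))
  }
  withCore <- mk(0.3)
  without <- mk(0)
  expect_gt(withCore, 10)
  expect_gt(withCore, without)
})

test_that("planted phylostratum ranks are recovered exactly", {
  cfg <- simulationConfig(nLayers = 4, genesPerLayer = 80, meanDegree = 5,
                          seed = 17)
  sim <- simulateMultilayer(cfg)
  rt <- rankTree(sim$tree, sim$truth$focal)
  focalGenes <- sim$truth$genes[sim$truth$genes$species == sim$truth$focal, ]
  ps <- assignPhylostrata(sim$orthogroups, rt,
                          orphanGenes = focalGenes$gene)
  expect_identical(unname(ps[focalGenes$gene]), focalGenes$rank)
})

test_that("expression carries the planted age-by-stage trend", {
  cfg <- simulationConfig(nLayers = 3, genesPerLayer = 200, meanDegree = 5,
                          stageAgeSlope = 0.5, seed = 23)
  sim <- simulateMultilayer(cfg)
  rt <- rankTree(sim$tree, "sp1")
  focalGenes <- sim$truth$genes[sim$truth$genes$species == "sp1", ]
  ps <- setNames(focalGenes$rank, focalGenes$gene)

  increasing <- vapply(1:40, function(s) {
    ex <- simulateExpression(sim$truth, seed = 5000 + s)
    g <- tai(ex$se, ps, cutoff = 0, by = "group")$groups$tai
    all(diff(g) > 0)
  }, logical(1))
  expect_gte(mean(increasing), 0.95)

  # zero slope: stage TAIs agree within Monte-Carlo error
  cfg0 <- simulationConfig(nLayers = 3, genesPerLayer = 200,
                           meanDegree = 5, stageAgeSlope = 0, seed = 23)
  sim0 <- simulateMultilayer(cfg0)
  fg0 <- sim0$truth$genes[sim0$truth$genes$species == "sp1", ]
  ex0 <- simulateExpression(sim0$truth, seed = 9)
  expect_true(all(SummarizedExperiment::assay(ex0$se, "tpm") >= 0))
  g0 <- tai(ex0$se, setNames(fg0$rank, fg0$gene), cutoff = 0,
            by = "group")$groups$tai
  expect_lt(max(g0) - min(g0), 0.15)
})

test_that("DEG sampling respects fraction, bias, and seed", {
  cfg <- simulationConfig(nLayers = 2, genesPerLayer = 1000,
                          conservedFraction = 0.5, paralogRate = 0,
                          partialFraction = 0, meanDegree = 5, seed = 12)
  sim <- simulateMultilayer(cfg)
  expect_length(simulateDeg(sim$truth, degFraction = 0), 0)

  deg <- simulateDeg(sim$truth, degFraction = 0.3, biasToCore = 1,
                     seed = 2)
  expect_length(deg, 300)
  focal <- sim$truth$genes[sim$truth$genes$species == "sp1", ]
  consShare <- mean(focal$conserved[match(deg, focal$gene)])
  p <- mean(focal$conserved)
  expect_lt(abs(consShare - p), 3 * sqrt(p * (1 - p) / 300))

  expect_identical(simulateDeg(sim$truth, seed = 7),
                   simulateDeg(sim$truth, seed = 7))

  biased <- simulateDeg(sim$truth, degFraction = 0.3, biasToCore = 5,
                        seed = 2)
  expect_gt(mean(focal$conserved[match(biased, focal$gene)]), consShare)
})
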