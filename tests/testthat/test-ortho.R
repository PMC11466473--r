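# two mirrored path layers A-B-C with 1:1 orthologs, used in several tests
mirrorToy <- function(dropEdge2 = NULL) {
  mk <- function(sp, drop = NULL) {
    e <- data.frame(gene_a = paste0(c("A", "B"), sp),
                    gene_b = paste0(c("B", "C"), sp),
                    score = c(0.8, 0.8), stringsAsFactors = FALSE)
    if (!is.null(drop)) e <- e[-drop, , drop = FALSE]
    toyLayer(e, species = sp, genes = paste0(c("A", "B", "C"), sp))
  }
  layers <- list(L1 = mk("L1"), L2 = mk("L2", dropEdge2))
  og <- data.frame(
    orthogroup = rep(c("OGA", "OGB", "OGC"), each = 2),
    species = rep(c("L1", "L2"), 3),
    gene = c("AL1", "AL2", "BL1", "BL2", "CL1", "CL2"),
    stringsAsFactors = FALSE)
  linkLayers(og, layers)
}

test_that("interlayer links follow orthogroups, including paralogs", {
  layers <- list(
    sp1 = toyLayer(data.frame(gene_a = "A1", gene_b = "B1", score = 0.9),
                   species = "sp1", genes = c("A1", "B1", "X1")),
    sp2 = toyLayer(data.frame(gene_a = "A2", gene_b = "B2a", score = 0.9),
                   species = "sp2", genes = c("A2", "B2a", "B2b")))
  og <- data.frame(
    orthogroup = c("OGA", "OGA", "OGB", "OGB", "OGB"),
    species = c("sp1", "sp2", "sp1", "sp2", "sp2"),
    gene = c("A1", "A2", "B1", "B2a", "B2b"), stringsAsFactors = FALSE)
  ml <- linkLayers(og, layers)
  links <- mlLinks(ml)
  bLinks <- links[links$gene_a == "B1" | links$gene_b == "B1", ]
  expect_setequal(c(bLinks$gene_a, bLinks$gene_b),
                  c("B1", "B2a", "B2b"))          # one-to-many paralogs
  # X1 is in no orthogroup: zero links, not conserved
  expect_equal(sum(links$gene_a == "X1" | links$gene_b == "X1"), 0L)
  cons <- conservedNodes(mlLayers(ml)$sp1)
  expect_false(cons[["X1"]])
  expect_true(cons[["A1"]] && cons[["B1"]])

  expect_error(linkLayers(og[og$species == "sp1", ], layers),
               "absent from the orthogroup")
})

test_that("perfectly mirrored backbones are fully retained", {
  ml <- computeBackbones(mirrorToy())
  ob <- extractOrthoBackbone(ml)
  expect_equal(nrow(obEdges(ob, "L1")), 2L)
  expect_equal(nrow(obEdges(ob, "L2")), 2L)
  expect_setequal(obNodes(ob, "L1"), c("AL1", "BL1", "CL1"))
  # orthoBackbone edges are a subset of each layer's backbone
  for (sp in c("L1", "L2")) {
    bbK <- obKeys(ob, sp)
    g <- backboneGraph(mlBackbones(ml)[[sp]])
    el <- igraph::as_edgelist(g)
    expect_true(all(bbK %in% paste(pmin(el[, 1], el[, 2]),
                                   pmax(el[, 1], el[, 2]))))
  }
})

test_that("a missing analog drops the edge and its stranded node everywhere", {
  ml <- computeBackbones(mirrorToy(dropEdge2 = 2))   # L2 lacks B-C
  ob <- extractOrthoBackbone(ml)
  expect_equal(obKeys(ob, "L1"), "AL1 BL1")
  expect_equal(obKeys(ob, "L2"), "AL2 BL2")
  expect_false("CL1" %in% obNodes(ob, "L1"))
  expect_false("CL2" %in% obNodes(ob, "L2"))

  expect_error(extractOrthoBackbone(mirrorToy()), "computeBackbones")
})

test_that("one backbone analog among paralogs suffices; paralog self-pairs do not", {
  # L2: A'-B'' metric (distance 0), B'-B'' distance 0, A'-B' semi-metric
  l1 <- toyLayer(data.frame(gene_a = "A", gene_b = "B", score = 0.8),
                 species = "L1")
  l2 <- toyLayer(data.frame(gene_a = c("Ap", "Bp", "Ap"),
                            gene_b = c("Bpp", "Bpp", "Bp"),
                            score = c(1, 1, 0.5), stringsAsFactors = FALSE),
                 species = "L2")
  og <- data.frame(orthogroup = c("OGA", "OGA", "OGB", "OGB", "OGB"),
                   species = c("L1", "L2", "L1", "L2", "L2"),
                   gene = c("A", "Ap", "B", "Bp", "Bpp"),
                   stringsAsFactors = FALSE)
  ml <- computeBackbones(linkLayers(og, list(L1 = l1, L2 = l2)))
  expect_false(all(metricFlags(mlBackbones(ml)$L2)))  # A'-B' semi-metric
  ob <- extractOrthoBackbone(ml)
  expect_equal(obKeys(ob, "L1"), "A B")     # retained via A'-B''
  # B'-B'' maps only onto the single gene B: no a' != b' pair, dropped
  expect_false("Bp Bpp" %in% obKeys(ob, "L2"))
})

test_that("orthoBackbone equals brute-force enumeration on random toys", {
  for (s in 1:20) {
    cfg <- simulationConfig(nLayers = sample(2:3, 1), genesPerLayer = 15,
                            meanDegree = 4, paralogRate = 0.3, seed = s)
    sim <- simulateMultilayer(cfg)
    ml <- computeBackbones(linkLayers(sim$orthogroups, sim$layers))
    ob <- extractOrthoBackbone(ml)
    brute <- bruteOrthoBackbone(sim$orthogroups, mlLayers(ml),
                                mlBackbones(ml))
    for (sp in names(mlLayers(ml)))
      expect_identical(obKeys(ob, sp), brute[[sp]])
  }
})

test_that("layer order does not change the orthoBackbone", {
  cfg <- simulationConfig(nLayers = 3, genesPerLayer = 20, meanDegree = 4,
                          seed = 99)
  sim <- simulateMultilayer(cfg)
  ob1 <- extractOrthoBackbone(computeBackbones(
    linkLayers(sim$orthogroups, sim$layers)))
  ob2 <- extractOrthoBackbone(computeBackbones(
    linkLayers(sim$orthogroups, rev(sim$layers))))
  for (sp in names(sim$layers))
    expect_identical(obKeys(ob1, sp), obKeys(ob2, sp))
})

test_that("three-way orthoBackbone is nested in the pairwise one", {
  cfg <- simulationConfig(nLayers = 3, genesPerLayer = 25, meanDegree = 5,
                          seed = 123)
  sim <- simulateMultilayer(cfg)
  ob3 <- extractOrthoBackbone(computeBackbones(
    linkLayers(sim$orthogroups, sim$layers)))
  ob2 <- extractOrthoBackbone(computeBackbones(
    linkLayers(sim$orthogroups, sim$layers[c("sp1", "sp2")])))
  for (sp in c("sp1", "sp2"))
    expect_true(all(obKeys(ob3, sp) %in% obKeys(ob2, sp)))
})

test_that("edge Jaccard handles identity, disjointness, and overlap", {
  ab <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"))
  expect_equal(edgeJaccard(ab, ab), 1.0)
  cd <- data.frame(gene_a = "C", gene_b = "D")
  expect_equal(edgeJaccard(ab, cd), 0.0)
  # {AB, BC} vs {AB, CD} -> 1/3; orientation must not matter
  acd <- data.frame(gene_a = c("B", "C"), gene_b = c("A", "D"))
  expect_equal(edgeJaccard(ab, acd), 1 / 3)
  none <- data.frame(gene_a = character(), gene_b = character())
  expect_warning(j <- edgeJaccard(none, none), "empty")
  expect_equal(j, 0)
})

test_that("core selection requires the annotation intersection by default", {
  edges <- data.frame(gene_a = c("A", "B", "D"), gene_b = c("B", "C", "E"),
                      stringsAsFactors = FALSE)
  x <- c("A", "B", "D"); y <- c("A", "C", "E")
  core <- selectCore(edges, x, y)      # intersection = {A}
  expect_equal(nrow(core), 1L)
  expect_equal(core$gene_a, "A")
  expect_equal(nrow(selectCore(edges, x, character())), 0L)
  # alternative reading: one endpoint in each set
  each <- selectCore(edges, x, y, mode = "each-set")
  expect_setequal(paste(each$gene_a, each$gene_b),
                  c("A B", "B C", "D E"))
})

test_that("edge disruption fractions and their monotonicity", {
  path <- data.frame(gene_a = c("A", "B", "C", "D"),
                     gene_b = c("B", "C", "D", "E"),
                     stringsAsFactors = FALSE)
  expect_equal(edgeDisruption(path, character())$fraction, 0)
  expect_equal(edgeDisruption(path, LETTERS[1:5])$fraction, 1)
  expect_equal(edgeDisruption(path, "B")$fraction, 0.5)
  expect_error(edgeDisruption(path[0, ], "B"), "empty")

  set.seed(4)
  for (i in 1:10) {
    nodes <- paste0("n", 1:15)
    e <- data.frame(gene_a = sample(nodes, 20, TRUE),
                    gene_b = sample(nodes, 20, TRUE))
    e <- e[e$gene_a != e$gene_b, ]
    small <- sample(nodes, 4); big <- union(small, sample(nodes, 5))
    expect_lte(edgeDisruption(e, small)$fraction,
               edgeDisruption(e, big)$fraction)
  }

  ht <- disruptionTest(edgeDisruption(path, "B"),
                       edgeDisruption(path, LETTERS[1:5]))
  expect_s3_class(ht, "htest")
  expect_match(ht$method, "Fisher")
})
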