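test_that("ranking the root-to-focal path follows root-to-leaf order", {
  rt <- rankTree("((A,B),C);", "A")
  sr <- strataRanks(rt)
  expect_equal(sr$rank, 1:3)
  expect_equal(sr$label[3], "A")
  expect_equal(slot(rt, "K"), 3L)

  expect_error(rankTree("((A,B),C);", "Z"), "not a leaf")
  expect_error(rankTree("(A,B,C);", "A"), "rooted")
})

test_that("orthogroups map to the oldest clade; orphans to rank K", {
  rt <- rankTree("((A,B),C);", "A")
  og <- data.frame(
    orthogroup = c("OG1", "OG1", "OG2", "OG3", "OG3"),
    species = c("A", "C", "A", "A", "B"),
    gene = c("a1", "c1", "a2", "a3", "b1"),
    stringsAsFactors = FALSE)
  ps <- assignPhylostrata(og, rt, orphanGenes = c("a1", "a2", "a3", "a9"))
  expect_equal(unname(ps["a1"]), 1L)   # spans A and C -> root
  expect_equal(unname(ps["a2"]), 3L)   # focal-only -> species-specific
  expect_equal(unname(ps["a3"]), 2L)   # spans A and B -> (A,B) clade
  expect_equal(unname(ps["a9"]), 3L)   # orphan -> rank K

  ogBad <- data.frame(orthogroup = "OG1", species = "Z", gene = "z1",
                      stringsAsFactors = FALSE)
  expect_error(assignPhylostrata(ogBad, rt), "not in tree")
})

test_that("phylostratum assignment matches the clade-scan oracle on random trees", {
  for (s in 1:30) {
    nLeaves <- sample(4:12, 1)
    tr <- randomTree(nLeaves, seed = s)
    focal <- tr$tip.label[1]
    rt <- rankTree(tr, focal)
    # random orthogroups always containing the focal species
    nOg <- 8
    og <- do.call(rbind, lapply(seq_len(nOg), function(k) {
      others <- sample(setdiff(tr$tip.label, focal),
                       sample(0:(nLeaves - 1), 1))
      spp <- c(focal, others)
      data.frame(orthogroup = paste0("OG", k), species = spp,
                 gene = paste0(spp, "_g", k), stringsAsFactors = FALSE)
    }))
    ps <- assignPhylostrata(og, rt)
    for (k in seq_len(nOg)) {
      spp <- og$species[og$orthogroup == paste0("OG", k)]
      expected <- scanRank(rt, spp)
      got <- unname(ps[paste0(focal, "_g", k)])
      expect_identical(got, as.integer(expected))
    }
  }
})

test_that("TAI matches hand computation and is scale invariant", {
  mat <- matrix(c(3, 1), nrow = 2, dimnames = list(c("g1", "g2"), "s1"))
  se <- toySE(mat, c(s1 = "grp"))
  ps <- c(g1 = 1L, g2 = 4L)
  res <- tai(se, ps, cutoff = 0)
  expect_equal(res$samples$tai, 7 / 4)
  expect_equal(sum(res$contributions[, 1]), 1, tolerance = 1e-9)

  res10 <- tai(toySE(mat * 10, c(s1 = "grp")), ps, cutoff = 0)
  expect_equal(res10$samples$tai, res$samples$tai, tolerance = 1e-12)

  # degenerate: all included genes rank 1
  resOne <- tai(se, c(g1 = 1L, g2 = 1L), cutoff = 0)
  expect_equal(resOne$samples$tai, 1.0)

  expect_error(tai(se, ps, cutoff = 100), "empty transcriptome")
})

test_that("raising the rank of an included gene cannot decrease TAI", {
  set.seed(5)
  mat <- matrix(runif(20, 1.5, 50), nrow = 10,
                dimnames = list(paste0("g", 1:10), c("s1", "s2")))
  se <- toySE(mat, c(s1 = "x", s2 = "x"))
  ps <- setNames(sample(1:5, 10, replace = TRUE), rownames(mat))
  base <- tai(se, ps)$samples$tai
  ps2 <- ps; ps2["g3"] <- ps["g3"] + 2L
  bumped <- tai(se, ps2)$samples$tai
  expect_true(all(bumped >= base - 1e-12))
})

test_that("conserved fraction counts old-strata genes among the expressed", {
  mat <- matrix(c(5, 5, 5, 5, 0.2), nrow = 5,
                dimnames = list(paste0("g", 1:5), "s1"))
  se <- toySE(mat, c(s1 = "grp"))
  ps <- c(g1 = 1L, g2 = 2L, g3 = 6L, g4 = 7L, g5 = 1L)
  # g5 not expressed; 2 of 4 expressed genes in ranks 1..5
  res <- conservedFraction(se, ps, oldRanks = 1:5)
  expect_equal(res$fractions$fraction, 0.5)
  expect_equal(res$fractions$n_expressed, 4L)

  allOld <- conservedFraction(se, setNames(rep(3L, 5), rownames(mat)))
  expect_equal(allOld$fractions$fraction, 1.0)

  none <- conservedFraction(se, ps, oldRanks = integer())
  expect_equal(none$fractions$fraction, 0.0)
})

test_that("conserved fraction is monotone in the old-rank set and supports group tests", {
  set.seed(11)
  mat <- matrix(runif(60, 0, 20), nrow = 10,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  se <- toySE(mat, setNames(rep(c("germ", "soma"), each = 3),
                            paste0("s", 1:6)))
  ps <- setNames(sample(1:6, 10, replace = TRUE), rownames(mat))
  f1 <- conservedFraction(se, ps, oldRanks = 1:2)$fractions$fraction
  f2 <- conservedFraction(se, ps, oldRanks = 1:4)$fractions$fraction
  expect_true(all(f2 >= f1))
  expect_true(all(f1 >= 0 & f2 <= 1))

  res <- conservedFraction(se, ps, compare = c("germ", "soma"))
  expect_s3_class(res$test, "htest")
  expect_match(res$test$method, "Wilcoxon")
})
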