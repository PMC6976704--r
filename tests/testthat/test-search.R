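test_that("random addition is deterministic and recovers clean signal", {
  sim <- randomInstance(8, 30, seed = 1)
  cfg <- searchConfig(seed = 1)
  t1 <- randomAdditionTree(sim@matrix, cfg, seed = 99)
  t2 <- randomAdditionTree(sim@matrix, cfg, seed = 99)
  expect_equal(rfDistance(t1, t2), 0L)

  m3 <- characterMatrix(matrix("0", 3, 1), c("A", "B", "C"))
  tr3 <- randomAdditionTree(m3, cfg, seed = 1)
  expect_setequal(tr3$tip.label, c("A", "B", "C"))
  m2 <- characterMatrix(matrix("0", 2, 1), c("A", "B"))
  expect_error(randomAdditionTree(m2, cfg), "at least 3")

  # strong homoplasy-free-ish signal: stepwise addition alone finds the truth
  sim <- simulateMatrix(simConfig(nTaxa = 12, nChars = 500, changeRate = 1,
                                  seed = 7))
  tr <- randomAdditionTree(sim@matrix, searchConfig(), seed = 5)
  expect_equal(rfDistance(tr, sim@trueTree), 0L)
})

test_that("TBR search attains the exhaustive optimum on 6-7 taxon instances", {
  topos7 <- allTopologies(sprintf("t%02d", 1:7))
  expect_length(topos7, 945)
  for (seed in 1:10) {
    sim <- randomInstance(7, 6, rate = 2.5, seed = 400 + seed)
    m <- sim@matrix
    # equal weights
    exhaust <- min(vapply(topos7, treeLength, integer(1), x = m))
    cfg <- searchConfig("equal_weights", replicates = 2, seed = seed)
    res <- runSearch(m, cfg)
    expect_equal(res@bestScore, exhaust, info = paste("seed", seed))
    # implied weighting
    exhaustF <- max(vapply(topos7, function(t) iwFit(t, m, 3)@totalFit,
                           numeric(1)))
    cfgI <- searchConfig(k = 3, replicates = 2, seed = seed)
    resI <- runSearch(m, cfgI)
    expect_equal(resI@bestScore, exhaustF, tolerance = 1e-9,
                 info = paste("seed", seed))
  }
})

test_that("a globally optimal start tree is a TBR fixed point", {
  sim <- randomInstance(6, 8, rate = 2, seed = 17)
  m <- sim@matrix
  topos <- allTopologies(taxonLabels(m))
  len <- vapply(topos, treeLength, integer(1), x = m)
  best <- topos[[which.min(len)]]
  res <- tbrSearch(best, m, searchConfig("equal_weights"))
  expect_equal(res@bestScore, min(len))
  expect_equal(rfDistance(res@bestTrees[[1]], best), 0L)
  expect_equal(res@log$swaps, 0)
  # every buffered tree attains the best score exactly
  for (tr in res@bestTrees)
    expect_equal(treeLength(tr, m), as.integer(min(len)))
})

test_that("the generated TBR neighborhood matches the move definition", {
  for (seed in c(2, 5)) {
    set.seed(seed)
    tr <- ape::rtopology(6, rooted = FALSE, tip.label = letters[1:6])
    nb <- tbrNeighbors(tr)
    keysMine <- sort(vapply(nb, topoKeyOracle, ""))
    expect_false(anyDuplicated(keysMine) > 0)
    all105 <- allTopologies(letters[1:6])
    keysOracle <- sort(vapply(
      Filter(function(t2) isTbrNeighbor(tr, t2), all105), topoKeyOracle, ""))
    expect_identical(keysMine, keysOracle)
  }
})

test_that("runSearch is a seed-deterministic merge of its replicates", {
  sim <- randomInstance(9, 25, rate = 2, seed = 3)
  m <- sim@matrix
  cfg <- searchConfig(k = 4, replicates = 3, seed = 11)
  r1 <- runSearch(m, cfg)
  r2 <- runSearch(m, cfg)
  expect_identical(r1@bestScore, r2@bestScore)
  expect_identical(lapply(r1@bestTrees, ape::write.tree),
                   lapply(r2@bestTrees, ape::write.tree))
  expect_identical(r1@log, r2@log)

  # replicates = 1 is exactly addition + TBR under the derived seed
  cfg1 <- searchConfig(k = 4, replicates = 1, seed = 11)
  rs <- runSearch(m, cfg1)
  set.seed(11)
  repSeed <- sample.int(.Machine$integer.max - 1L, 1)
  set.seed(repSeed)
  start <- randomAdditionTree(m, cfg1)
  comp <- tbrSearch(start, m, cfg1)
  expect_equal(rs@bestScore, comp@bestScore)
  expect_equal(rfDistance(rs@bestTrees[[1]], comp@bestTrees[[1]]), 0L)
})

test_that("strict consensus retains exactly the shared bipartitions", {
  sim <- randomInstance(8, 12, rate = 2, seed = 21)
  trees <- runSearch(sim@matrix,
                     searchConfig("equal_weights", replicates = 4,
                                  seed = 2))@bestTrees
  single <- strictConsensus(trees[1])
  expect_equal(rfDistance(single, trees[[1]]), 0L)

  cons <- strictConsensus(trees)
  shared <- Reduce(intersect, lapply(trees, bipartSet))
  expect_setequal(bipartSet(cons), shared)

  # two trees sharing nothing give a star
  a <- ape::read.tree(text = "((x1,x2),((x3,x4),(x5,x6)));")
  b <- ape::read.tree(text = "((x1,x4),((x2,x6),(x3,x5)));")
  expect_length(bipartSet(ape::unroot(a)), 3)
  star <- strictConsensus(c(a, b))
  expect_equal(star$Nnode, 1L)

  bad <- ape::read.tree(text = "((x1,x9),(x3,x4));")
  expect_error(strictConsensus(c(a, bad)), "leaf set")
})

test_that("RF distance counts bipartition symmetric differences", {
  a <- ape::read.tree(text = "((p,q),(r,s));")
  expect_equal(rfDistance(a, a), 0L)
  b <- ape::read.tree(text = "((p,r),(q,s));")
  expect_equal(rfDistance(a, b), 2L)  # 2(n-3) attained at n = 4
  for (seed in 1:6) {
    set.seed(seed)
    t1 <- ape::rtopology(8, rooted = FALSE, tip.label = letters[1:8])
    t2 <- ape::rtopology(8, rooted = FALSE, tip.label = letters[1:8])
    sym <- length(union(setdiff(bipartSet(t1), bipartSet(t2)),
                        setdiff(bipartSet(t2), bipartSet(t1))))
    expect_equal(rfDistance(t1, t2), sym)
  }
  expect_error(rfDistance(a, ape::read.tree(text = "((p,q),(r,z));")),
               "leaf set")
})
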