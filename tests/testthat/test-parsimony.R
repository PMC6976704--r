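quartet <- function(states) {
  characterMatrix(matrix(states, 4, 1), c("A", "B", "C", "D"))
}
tree_abcd <- ape::read.tree(text = "((A,B),(C,D));")

test_that("fitch step counts on hand-checkable quartets", {
  expect_equal(fitchSteps(tree_abcd, quartet(c("0", "0", "0", "0")), 1), 0L)
  expect_equal(fitchSteps(tree_abcd, quartet(c("0", "0", "1", "1")), 1), 1L)
  # A=0,B=1,C=0,D=1: verified against exhaustive internal-state enumeration
  m <- quartet(c("0", "1", "0", "1"))
  expect_equal(oracleFitchLength(tree_abcd, allowedStates(tree_abcd, m, 1), 2),
               2)
  expect_equal(fitchSteps(tree_abcd, m, 1), 2L)
  expect_error(fitchSteps(tree_abcd, m, 7), "out of range")
})

test_that("step counts are invariant under rooting", {
  for (seed in 1:8) {
    sim <- randomInstance(7, 5, nStates = 3, seed = seed)
    m <- sim@matrix
    tr <- sim@trueTree
    ref <- characterSteps(tr, m)
    for (og in sample(tr$tip.label, 3)) {
      expect_equal(characterSteps(rootOnOutgroup(tr, og), m), ref)
    }
  }
})

test_that("fitch equals exhaustive enumeration on random instances", {
  for (seed in 1:30) {
    n <- 4 + (seed %% 4)
    sim <- randomInstance(n, 4, nStates = 2 + seed %% 2, seed = 100 + seed)
    m <- sim@matrix
    tr <- sim@trueTree
    for (ch in seq_len(nCharacters(m))) {
      expect_equal(
        fitchSteps(tr, m, ch),
        as.integer(oracleFitchLength(tr, allowedStates(tr, m, ch),
                                     characterInfo(m)$n_states[ch])),
        info = sprintf("seed %d char %d", seed, ch))
    }
  }
})

test_that("tree length sums per-character steps and matches phangorn", {
  m <- loadPackagedMatrix()
  set.seed(42)
  tr <- ape::rtopology(nTaxa(m), rooted = FALSE, tip.label = taxonLabels(m))
  expect_equal(treeLength(tr, m), sum(characterSteps(tr, m)))

  # independent engine: phangorn's Fitch kernel on the same data
  library(phangorn)
  tok <- cladiw:::.cellTokens(m)
  rownames(tok) <- taxonLabels(m)
  allTok <- sort(unique(as.vector(tok)))
  contrast <- t(sapply(allTok, function(tk) {
    if (tk %in% c("?", "-")) rep(1, 5)
    else as.numeric(0:4 %in% as.integer(strsplit(gsub("[^0-9]", "", tk),
                                                 "")[[1]]))
  }))
  colnames(contrast) <- as.character(0:4)
  pd <- phyDat(tok, type = "USER", contrast = contrast)
  expect_equal(treeLength(tr, m), as.integer(parsimony(tr, pd)))

  # all-constant matrix scores zero
  cm <- characterMatrix(matrix("1", 5, 3), letters[1:5])
  tr5 <- ape::read.tree(text = "((a,b),(c,(d,e)));")
  expect_equal(treeLength(tr5, cm), 0L)
})

test_that("minSteps counts only unambiguous observations", {
  m <- loadPackagedMatrix()
  expect_equal(minSteps(m, 6), 2L)   # three states, all seen unambiguously
  toks <- cbind(c("0", "1", "2", "1"),   # u = 3
                c("?", "?", "?", "?"),   # entirely missing
                c("[01]", "?", "[01]", "-"),  # polymorphic-only
                c("0", "0", "[01]", "1"))     # u = 2 despite polymorphism
  mm <- characterMatrix(toks, c("A", "B", "C", "D"))
  expect_equal(minSteps(mm), c(2L, 0L, 0L, 1L))
})

test_that("implied-weighting fit identities, bounds and errors", {
  mini <- fixtureMiniatures()[[2]]  # homoplasy-free instance
  for (k in c(0.3, 3, 20)) {
    rep <- iwFit(mini$tree, mini$matrix, k)
    expect_equal(rep@totalFit, nCharacters(mini$matrix))
    expect_equal(rep@complement, 0)
  }
  # a character with exactly 4 extra steps contributes 4/(4+4) = 0.5
  st <- rep(c("0", "1"), 5)
  comb <- ape::read.tree(text = paste0("(t1,(t2,(t3,(t4,(t5,(t6,(t7,(t8,(t9,",
                                       "t10)))))))));"))
  m10 <- characterMatrix(matrix(st, 10, 1), paste0("t", 1:10))
  rep <- iwFit(comb, m10, 4)
  expect_equal(rep@scores$steps, 5L)
  expect_equal(rep@scores$extra_steps, 4L)
  expect_equal(rep@scores$fit, 0.5)

  m <- loadPackagedMatrix()
  set.seed(7)
  tr <- ape::rtopology(nTaxa(m), rooted = FALSE, tip.label = taxonLabels(m))
  rep <- iwFit(tr, m, 4)
  expect_true(all(rep@scores$fit > 0 & rep@scores$fit <= 1))
  expect_true(all(rep@scores$extra_steps >= 0))
  expect_equal(rep@informativeFit,
               sum(rep@scores$fit[isInformative(m)]))
  expect_error(iwFit(tr, m, 0), "positive")
  expect_error(iwFit(tr, m, -2), "positive")
})

test_that("fit is monotone in per-character extra steps for every k", {
  # two fixed trees whose es vectors differ in exactly one character
  m <- fixtureMiniatures()[[3]]$matrix
  good <- fixtureMiniatures()[[3]]$tree        # char 2 fits with 1 step
  bad <- ape::read.tree(text = "((A,C),((B,D),(E,F)));")
  s1 <- characterSteps(good, m)
  s2 <- characterSteps(bad, m)
  stopifnot(any(s1 != s2))
  for (k in c(0.5, 1, 4, 50, 1e6)) {
    f1 <- iwFit(good, m, k)@totalFit
    f2 <- iwFit(bad, m, k)@totalFit
    expect_gt(f1, f2)
  }
})

test_that("large k ranks trees like equal-weights length", {
  for (seed in 1:6) {
    sim <- randomInstance(6, 8, rate = 2, seed = 300 + seed)
    m <- sim@matrix
    topos <- allTopologies(taxonLabels(m))[seq(1, 105, by = 7)]
    len <- vapply(topos, treeLength, integer(1), x = m)
    fit <- vapply(topos, function(t) iwFit(t, m, 1e6)@totalFit, numeric(1))
    for (i in seq_along(topos)) for (j in seq_along(topos))
      if (len[i] < len[j])
        expect_true(fit[i] > fit[j], label = paste("seed", seed))
  }
})
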