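test_that("outgroup rooting round-trips and places the root correctly", {
  set.seed(4)
  tr <- ape::rtopology(7, rooted = FALSE, tip.label = letters[1:7])
  rt <- rootOnOutgroup(tr, "d")
  expect_true(ape::is.rooted(rt))
  # root children: the outgroup leaf and the rest
  root <- length(rt$tip.label) + 1L
  kids <- rt$edge[rt$edge[, 1] == root, 2]
  expect_length(kids, 2)
  expect_true(any(kids <= 7 & rt$tip.label[pmin(kids, 7)] == "d"))
  expect_equal(rfDistance(ape::unroot(rt), tr), 0L)

  tr3 <- ape::read.tree(text = "(a,b,c);")
  rt3 <- rootOnOutgroup(tr3, "b")
  cherry <- ape::extract.clade(rt3, ape::getMRCA(rt3, c("a", "c")))
  expect_setequal(cherry$tip.label, c("a", "c"))
  expect_error(rootOnOutgroup(tr, "zz"), "absent")
})

test_that("unambiguous changes on hand-checkable instances", {
  minis <- fixtureMiniatures()

  # constant character: no changes anywhere
  cm <- characterMatrix(matrix("1", 4, 1), c("A", "B", "C", "D"))
  rt <- rootOnOutgroup(ape::read.tree(text = "((A,B),(C,D));"), "A")
  expect_equal(nrow(unambiguousChanges(rt, cm)), 0)

  # single synapomorphy maps to the branch below the derived cherry
  m1 <- minis[[1]]$matrix
  rt1 <- rootOnOutgroup(minis[[1]]$tree, "A")
  ch1 <- unambiguousChanges(rt1, m1)
  expect_equal(nrow(ch1), 1)
  expect_equal(ch1$from, 0L)
  expect_equal(ch1$to, 1L)
  cs <- cladeSupport(rt1, m1, c("C", "D"))
  expect_true(cs@foundMonophyletic)
  expect_equal(nrow(cs@changes), 1)
  expect_equal(cs@changes$apo_class, "global")

  # convergent state: both origins classified local
  m3 <- minis[[3]]$matrix
  rt3 <- rootOnOutgroup(minis[[3]]$tree, "A")
  ch3 <- classifyApomorphies(unambiguousChanges(rt3, m3), rt3, m3)
  conv <- ch3[ch3$char_index == 1, ]
  expect_equal(nrow(conv), 2)
  expect_setequal(conv$child_label, c("C", "E"))
  expect_equal(unique(conv$apo_class), "local")
  # the clean character on the same tree is global
  clean <- ch3[ch3$char_index == 2, ]
  expect_equal(clean$apo_class, "global")

  expect_error(unambiguousChanges(ape::unroot(minis[[3]]$tree), m3),
               "rooted")
})

test_that("changes and classes match exhaustive MPR enumeration", {
  nInst <- 30
  for (seed in seq_len(nInst)) {
    n <- 4 + (seed %% 3)
    sim <- randomInstance(n, 3, nStates = 2 + (seed %% 2), rate = 2,
                          missing = 0.15, inapplicable = 0.05,
                          seed = 500 + seed)
    m <- sim@matrix
    rt <- rootOnOutgroup(sim@trueTree, taxonLabels(m)[1])
    mine <- classifyApomorphies(unambiguousChanges(rt, m), rt, m)
    for (ch in seq_len(nCharacters(m))) {
      orc <- oracleMPR(rt, m, ch)
      got <- mine[mine$char_index == ch, c("parent", "child", "from", "to",
                                           "apo_class")]
      want <- orc$changes[, c("parent", "child", "from", "to", "apo_class")]
      got <- got[order(got$parent, got$child), ]
      want <- want[order(want$parent, want$child), ]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, info = sprintf("seed %d char %d", seed, ch))
      # conservation: steps of every explicit MPR equal the Fitch count
      expect_equal(orc$best,
                   oracleFitchLength(rt, allowedStates(rt, m, ch),
                                     characterInfo(m)$n_states[ch]))
      expect_lte(nrow(got), orc$best)
    }
  }
})

test_that("per-character unambiguous changes never exceed the step count", {
  m <- loadPackagedMatrix()
  set.seed(9)
  tr <- ape::rtopology(nTaxa(m), rooted = FALSE, tip.label = taxonLabels(m))
  rt <- rootOnOutgroup(tr, "Musca_spp")
  ch <- unambiguousChanges(rt, m)
  steps <- characterSteps(rt, m)
  cnt <- table(factor(ch$char_index, levels = seq_len(nCharacters(m))))
  expect_true(all(as.integer(cnt) <= steps))
  # canonical ordering by branch then character
  expect_false(is.unsorted(order(ch$parent, ch$child, ch$char_index)))
  # a global apomorphy arises exactly once on the tree
  cls <- classifyApomorphies(ch, rt, m)
  glb <- cls[cls$apo_class == "global", ]
  if (nrow(glb)) {
    key <- paste(glb$char_index, glb$to)
    expect_false(anyDuplicated(key) > 0)
  }
})

test_that("cladeSupport detects monophyly and non-monophyly", {
  sim <- randomInstance(8, 20, seed = 61)
  m <- sim@matrix
  rt <- rootOnOutgroup(sim@trueTree, taxonLabels(m)[1])
  labs <- taxonLabels(m)
  # the full leaf set is trivially monophyletic, with no root-edge changes
  cs <- cladeSupport(rt, m, labs)
  expect_true(cs@foundMonophyletic)
  expect_equal(nrow(cs@changes), 0)
  # a genuine clade from the tree
  po <- ape::reorder.phylo(rt, "postorder")
  inner <- po$edge[po$edge[, 2] > 8, 2][1]
  cl <- ape::extract.clade(po, inner)$tip.label
  expect_true(cladeSupport(rt, m, cl)@foundMonophyletic)
  # a scrambled set is not
  scr <- c(cl[1], setdiff(labs, cl)[1:2])
  expect_false(cladeSupport(rt, m, scr)@foundMonophyletic)
  expect_error(cladeSupport(rt, m, character(0)), "empty")
  expect_error(cladeSupport(rt, m, c(labs[1], "nosuch")), "unknown")
})

test_that("zero-length-branch collapsing keeps supported branches", {
  m <- fixtureMiniatures()[[2]]$matrix
  rt <- rootOnOutgroup(fixtureMiniatures()[[2]]$tree, "A")
  col <- collapseZeroLength(rt, m)
  # nested characters support every internal branch here: nothing collapses
  expect_equal(col$Nnode, rt$Nnode)
  # a constant matrix collapses everything into a star below the root
  cm <- characterMatrix(matrix("0", 5, 2), LETTERS[1:5])
  rt2 <- rootOnOutgroup(ape::read.tree(text = "(A,(B,(C,(D,E))));"), "A")
  col2 <- collapseZeroLength(rt2, cm)
  expect_lt(col2$Nnode, rt2$Nnode)
})
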