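# Brute-force oracles, independent of the package's optimization engine:
# exhaustive topology enumeration, exhaustive internal-state enumeration for
# Fitch lengths, exhaustive MPR enumeration for unambiguous changes and
# global/local classes, and a definition-based TBR-neighborhood test.

# ---- topology enumeration --------------------------------------------------

.edgeToNewick <- function(ed, labels) {
  n <- length(labels)
  adj <- vector("list", max(ed))
  for (i in seq_len(nrow(ed))) {
    adj[[ed[i, 1]]] <- c(adj[[ed[i, 1]]], ed[i, 2])
    adj[[ed[i, 2]]] <- c(adj[[ed[i, 2]]], ed[i, 1])
  }
  rec <- function(v, p) {
    if (v <= n) return(labels[v])
    kids <- setdiff(adj[[v]], p)
    paste0("(", paste(vapply(kids, rec, "", p = v), collapse = ","), ")")
  }
  paste0(rec(adj[[1]][1], 0L), ";")  # written from tip 1's neighbour
}

# all unrooted binary topologies over the labels (feasible for n <= 7)
allTopologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3, n <= 8)
  edlist <- list(rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L)))
  for (t in seq_len(n)[-(1:3)]) {
    v <- n + t - 2L
    nxt <- vector("list", 0)
    for (ed in edlist) {
      for (e in seq_len(nrow(ed))) {
        nxt[[length(nxt) + 1L]] <-
          rbind(ed[-e, , drop = FALSE], c(ed[e, 1], v), c(v, ed[e, 2]),
                c(v, t))
      }
    }
    edlist <- nxt
  }
  lapply(edlist, function(ed) ape::read.tree(text = .edgeToNewick(ed, labels)))
}

# ---- canonical forms -------------------------------------------------------

# bipartition set of an unrooted tree: each internal edge as the sorted taxon
# subset on the side away from the alphabetically first label
bipartSet <- function(tree) {
  if (ape::is.rooted(tree) && length(tree$tip.label) > 3L)
    tree <- ape::unroot(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  ntip <- length(po$tip.label)
  ref <- sort(po$tip.label)[1]
  below <- vector("list", max(E))
  for (v in seq_len(ntip)) below[[v]] <- po$tip.label[v]
  for (e in seq_len(nrow(E)))
    below[[E[e, 1]]] <- c(below[[E[e, 1]]], below[[E[e, 2]]])
  out <- character(0)
  for (e in seq_len(nrow(E))) {
    ch <- E[e, 2]
    if (ch <= ntip) next
    s <- below[[ch]]
    if (length(s) <= 1L || length(s) >= ntip - 1L) next
    if (ref %in% s) s <- setdiff(po$tip.label, s)
    out <- c(out, paste(sort(s), collapse = "|"))
  }
  sort(unique(out))
}

topoKeyOracle <- function(tree) paste(bipartSet(tree), collapse = ";")

sameTopology <- function(a, b) identical(topoKeyOracle(a), topoKeyOracle(b))

# ---- exhaustive Fitch length ----------------------------------------------

# allowed: list over tree tips (tip order) of allowed state vectors
oracleFitchLength <- function(tree, allowed, nStates) {
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2L)
    tree <- ape::unroot(tree)
  E <- tree$edge
  ntip <- length(tree$tip.label)
  combos <- as.matrix(expand.grid(rep(list(0:(nStates - 1)), tree$Nnode)))
  cost <- numeric(nrow(combos))
  for (e in seq_len(nrow(E))) {
    p <- combos[, E[e, 1] - ntip]
    ch <- E[e, 2]
    if (ch <= ntip) cost <- cost + !(p %in% allowed[[ch]])
    else cost <- cost + (p != combos[, ch - ntip])
  }
  min(cost)
}

# allowed-state lists for character ch of matrix m, in tree tip order
allowedStates <- function(tree, m, ch) {
  S <- characterInfo(m)$n_states[ch]
  lapply(tree$tip.label, function(lb) {
    cs <- cellStates(m, lb, ch)
    if (cs$kind == "observed") cs$states else 0:(S - 1)
  })
}

# exhaustive tree length: minimum over all characters summed
oracleTreeLength <- function(tree, m) {
  sum(vapply(seq_len(nCharacters(m)), function(ch)
    oracleFitchLength(tree, allowedStates(tree, m, ch),
                      characterInfo(m)$n_states[ch]), numeric(1)))
}

oracleIwFit <- function(tree, m, k) {
  s <- vapply(seq_len(nCharacters(m)), function(ch)
    oracleFitchLength(tree, allowedStates(tree, m, ch),
                      characterInfo(m)$n_states[ch]), numeric(1))
  sum(k / (k + pmax(s - minSteps(m), 0)))
}

# ---- exhaustive MPR enumeration -------------------------------------------

# Enumerates every most-parsimonious assignment (internal nodes plus
# ambiguous tips) of character ch on the rooted tree; derives unambiguous
# branch changes and their global/local classes with the same root-edge and
# transparency conventions the package documents.
oracleMPR <- function(rtree, m, ch) {
  po <- ape::reorder.phylo(rtree, "postorder")
  E <- po$edge
  ntip <- length(po$tip.label)
  root <- E[nrow(E), 1]
  S <- characterInfo(m)$n_states[ch]
  allowed <- allowedStates(po, m, ch)
  ambTips <- which(lengths(allowed) > 1L)
  vars <- c(ntip + seq_len(po$Nnode), ambTips)
  domains <- c(rep(list(0:(S - 1)), po$Nnode), allowed[ambTips])
  combos <- as.matrix(expand.grid(domains))
  colOf <- function(v) {
    i <- match(v, vars)
    if (!is.na(i)) combos[, i] else rep(allowed[[v]][1], nrow(combos))
  }
  cost <- numeric(nrow(combos))
  for (e in seq_len(nrow(E))) cost <- cost + (colOf(E[e, 1]) != colOf(E[e, 2]))
  best <- min(cost)
  opt <- which(cost == best)
  # per edge: matrix of (parent state, child state) over optimal assignments
  pstates <- lapply(seq_len(nrow(E)), function(e) colOf(E[e, 1])[opt])
  cstates <- lapply(seq_len(nrow(E)), function(e) colOf(E[e, 2])[opt])
  # scanning conventions
  pend <- E[, 2] <= ntip
  scannable <- !(E[, 1] == root & pend)
  scannable[pend & (E[, 2] %in% ambTips)] <- FALSE
  # nodes below each node
  below <- vector("list", ntip + po$Nnode)
  for (v in seq_len(ntip)) below[[v]] <- v
  for (e in seq_len(nrow(E))) below[[E[e, 1]]] <- c(below[[E[e, 1]]], below[[E[e, 2]]], E[e, 2])
  changes <- list()
  for (e in seq_len(nrow(E))) {
    if (E[e, 1] == root) next  # root edge: not reportable
    pairs <- unique(cbind(pstates[[e]], cstates[[e]]))
    if (any(pairs[, 1] == pairs[, 2])) next
    if (nrow(pairs) != 1L) next  # ambiguous endpoints: excluded
    x <- pairs[1, 2]
    inSub <- c(below[[E[e, 2]]], E[e, 2])
    isLocal <- FALSE
    for (o in seq_along(opt)) {
      for (e2 in which(scannable)) {
        pp <- pstates[[e2]][o]; cc <- cstates[[e2]][o]
        if (e2 != e && pp != x && cc == x) isLocal <- TRUE       # convergence
        if (E[e2, 1] %in% inSub && pp == x && cc != x) isLocal <- TRUE  # reversal
      }
      if (isLocal) break
    }
    changes[[length(changes) + 1L]] <- data.frame(
      parent = E[e, 1], child = E[e, 2], char_index = ch,
      from = pairs[1, 1], to = x,
      apo_class = if (isLocal) "local" else "global")
  }
  res <- if (length(changes)) do.call(rbind, changes) else
    data.frame(parent = integer(), child = integer(), char_index = integer(),
               from = integer(), to = integer(), apo_class = character())
  list(best = best, changes = res, tree = po, nOpt = length(opt))
}

# ---- TBR neighborhood, from the definition --------------------------------

# T2 is one TBR move from T1 iff some taxon bipartition (A|B) is an edge
# split of both trees and the induced subtrees on A and on B agree.
isTbrNeighbor <- function(t1, t2) {
  if (sameTopology(t1, t2)) return(FALSE)
  labs <- t1$tip.label
  n <- length(labs)
  splits <- c(lapply(labs, function(x) x),                    # pendant cuts
              lapply(strsplit(bipartSet(t1), "|", fixed = TRUE), identity))
  for (A in splits) {
    B <- setdiff(labs, A)
    restrEq <- function(set) {
      if (length(set) <= 3L) return(TRUE)
      sameTopology(ape::keep.tip(t1, set), ape::keep.tip(t2, set))
    }
    # the split must be present in t2 as well (it is, by construction, iff
    # both restrictions match and the split is a split of t2)
    s2 <- c(lapply(labs, function(x) x),
            lapply(strsplit(bipartSet(t2), "|", fixed = TRUE), identity))
    has2 <- any(vapply(s2, function(s) setequal(s, A) || setequal(s, B),
                       TRUE))
    if (has2 && restrEq(A) && restrEq(B)) return(TRUE)
  }
  FALSE
}

# ---- misc ------------------------------------------------------------------

randomInstance <- function(nTaxa, nChars, nStates = 2, rate = 1.5,
                           missing = 0.1, inapplicable = 0.05, seed = 1) {
  simulateMatrix(simConfig(nTaxa = nTaxa, nChars = nChars, nStates = nStates,
                           changeRate = rate, missingRate = missing,
                           inapplicableRate = inapplicable, seed = seed))
}
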