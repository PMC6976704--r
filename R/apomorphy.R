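# Optimization of character-state changes on a rooted tree: unambiguous
# changes (present in every most-parsimonious reconstruction) and their
# classification as global (uncontradicted, unreversed) or local
# (convergent or reversed) apomorphies.

#' Root a tree on an outgroup taxon's pendant edge
#'
#' @param tree `phylo` (rooted input is unrooted first).
#' @param outgroup a leaf label.
#' @return rooted `phylo`; the root has two children, the outgroup leaf and
#'   the rest of the tree.
#' @export
rootOnOutgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup label absent from tree: ", outgroup)
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2L)
    tree <- ape::unroot(tree)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

# Per-character MPR cost tables on a rooted binary tree.
# For node v and state x, L[v,x] = min changes in v's subtree given x at v;
# Rex[e,y] = min changes outside child(e)'s subtree given y at parent(e).
# A state pair (y,x) on edge e is realized by some MPR iff
# Rex[e,y] + (y != x) + L[child,x] equals the character's minimum.
.mprTables <- function(tree, x) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  nNodes <- ntip + po$Nnode
  root <- E[nrow(E), 1]
  masks <- .engineMasks(x, taxa = po$tip.label)
  nst <- characterInfo(x)$n_states
  INF <- 1e9
  tables <- vector("list", nCharacters(x))
  for (ch in seq_len(nCharacters(x))) {
    S <- nst[ch]
    L <- matrix(0, nNodes, S)
    for (t in seq_len(ntip)) {
      allowed <- bitwAnd(masks[t, ch], bitwShiftL(1L, 0:(S - 1))) != 0L
      L[t, !allowed] <- INF
    }
    contrib <- matrix(0, nrow(E), S)
    for (e in seq_len(nrow(E))) {
      child <- E[e, 2]
      cc <- pmin(L[child, ], min(L[child, ]) + 1)
      contrib[e, ] <- cc
      L[E[e, 1], ] <- L[E[e, 1], ] + cc
    }
    best <- min(L[root, ])
    Rv <- matrix(INF, nNodes, S)
    Rv[root, ] <- 0
    Rex <- matrix(0, nrow(E), S)
    for (e in rev(seq_len(nrow(E)))) {
      rex <- Rv[E[e, 1], ] + L[E[e, 1], ] - contrib[e, ]
      Rex[e, ] <- rex
      Rv[E[e, 2], ] <- pmin(rex, min(rex) + 1)
    }
    tables[[ch]] <- list(S = S, L = L, Rex = Rex, best = best)
  }
  # node sets below each node (for reversal scanning)
  below <- vector("list", nNodes)
  for (v in seq_len(ntip)) below[[v]] <- v
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1]
    below[[p]] <- c(below[[p]], below[[E[e, 2]]])
  }
  for (v in seq_len(nNodes)) below[[v]] <- unique(c(below[[v]], v))
  list(tables = tables, edge = E, ntip = ntip, root = root, tree = po,
       masks = masks, below = below)
}

# logical S x S matrix: optimal (parent state, child state) pairs on edge e
.optPairs <- function(tb, ch, e) {
  t <- tb$tables[[ch]]
  child <- tb$edge[e, 2]
  C <- outer(t$Rex[e, ], t$L[child, ], "+") + (1 - diag(t$S))
  C <= t$best + 0.5
}

# edges eligible for convergence/reversal scanning of character ch:
# skip the root -> outgroup-leaf pendant edge (the other root-incident branch
# represents the same unrooted edge and is scanned once), and skip pendant
# edges to leaves without a single unambiguously observed state.
.scannableEdges <- function(tb, x, ch) {
  E <- tb$edge
  keep <- rep(TRUE, nrow(E))
  keep[E[, 1] == tb$root & E[, 2] <= tb$ntip] <- FALSE
  pendIdx <- which(E[, 2] <= tb$ntip)
  if (length(pendIdx)) {
    lab <- tb$tree$tip.label[E[pendIdx, 2]]
    idx <- match(lab, taxonLabels(x))
    single <- x@cellKind[cbind(idx, ch)] == "observed" &
      (x@stateMask[cbind(idx, ch)] %in% bitwShiftL(1L, 0:7))
    keep[pendIdx[!single]] <- FALSE
  }
  which(keep)
}

.emptyChanges <- function() {
  data.frame(parent = integer(), child = integer(),
             child_label = character(), char_index = integer(),
             from = integer(), to = integer(), unambiguous = logical(),
             stringsAsFactors = FALSE)
}

#' Unambiguous character-state changes on a rooted tree
#'
#' A change is reported on a branch when *every* most-parsimonious
#' reconstruction (MPR) assigns different states to its two ends, i.e. the
#' change is unambiguous under the optimization.  When the endpoints differ
#' in every MPR but the state pair varies across MPRs, the branch cannot be
#' rendered as a single "index:state" item; such cases are excluded from the
#' result and returned in the `"ambiguousEndpoint"` attribute.  The two
#' root-incident branches (the root edge) carry no reportable changes.
#'
#' @param tree rooted `phylo` (see [rootOnOutgroup()]).
#' @param x a [CharacterMatrix-class].
#' @return data.frame with columns parent, child (node ids of the returned
#'   postorder tree, also attached as attribute `"tree"`), child_label (for
#'   pendant branches), char_index, from, to, unambiguous.
#' @export
unambiguousChanges <- function(tree, x) {
  tb <- .mprTables(tree, x)
  E <- tb$edge
  report <- which(E[, 1] != tb$root)
  out <- list()
  amb <- list()
  for (ch in seq_len(nCharacters(x))) {
    if (tb$tables[[ch]]$best == 0) next
    for (e in report) {
      P <- .optPairs(tb, ch, e)
      idx <- which(P, arr.ind = TRUE)
      if (any(idx[, 1] == idx[, 2])) next  # some MPR keeps the state
      child <- E[e, 2]
      lab <- if (child <= tb$ntip) tb$tree$tip.label[child] else ""
      if (nrow(idx) == 1L) {
        out[[length(out) + 1L]] <- data.frame(
          parent = E[e, 1], child = child, child_label = lab,
          char_index = ch, from = idx[1, 1] - 1L, to = idx[1, 2] - 1L,
          unambiguous = TRUE, stringsAsFactors = FALSE)
      } else {
        amb[[length(amb) + 1L]] <- data.frame(
          parent = E[e, 1], child = child, child_label = lab,
          char_index = ch, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else .emptyChanges()
  res <- res[order(res$parent, res$child, res$char_index), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "ambiguousEndpoint") <-
    if (length(amb)) do.call(rbind, amb) else NULL
  attr(res, "tree") <- tb$tree
  res
}

#' Classify unambiguous changes as global or local apomorphies
#'
#' A change into state `x` on branch `b` is a *global* apomorphy when, over
#' the optimized tree, no most-parsimonious reconstruction gains state `x`
#' on any other branch (no convergence) and none loses it on a branch inside
#' `b`'s subtree (no reversal); otherwise it is *local*.  Branches to leaves
#' without a single unambiguous observation are transparent to the scan.
#'
#' @param changes result of [unambiguousChanges()] on the same tree/matrix.
#' @param tree the same rooted `phylo`.
#' @param x the same [CharacterMatrix-class].
#' @return `changes` with an added `apo_class` column ("global"/"local").
#' @export
classifyApomorphies <- function(changes, tree, x) {
  tb <- .mprTables(tree, x)
  E <- tb$edge
  cls <- character(nrow(changes))
  for (i in seq_len(nrow(changes))) {
    ch <- changes$char_index[i]
    xs <- changes$to[i] + 1L
    b <- which(E[, 1] == changes$parent[i] & E[, 2] == changes$child[i])
    scan <- .scannableEdges(tb, x, ch)
    S <- tb$tables[[ch]]$S
    inSub <- tb$below[[changes$child[i]]]
    local <- FALSE
    for (e in scan) {
      P <- .optPairs(tb, ch, e)
      if (e != b && any(P[-xs, xs])) { local <- TRUE; break }  # convergence
      if (E[e, 1] %in% inSub && any(P[xs, -xs])) { local <- TRUE; break }
    }
    cls[i] <- if (local) "local" else "global"
  }
  changes$apo_class <- cls
  changes
}

#' Apomorphy support of a taxon set
#'
#' Tests whether `cladeTaxa` form an exact clade on the rooted tree and, if
#' so, reports the unambiguous character-state changes on the clade's
#' subtending branch, classified and rendered in "index:state" notation.
#'
#' @param tree rooted `phylo`.
#' @param x a [CharacterMatrix-class].
#' @param cladeTaxa non-empty vector of leaf labels.
#' @return a [CladeSupport-class].
#' @export
cladeSupport <- function(tree, x, cladeTaxa) {
  if (!length(cladeTaxa)) stop("empty clade set")
  if (anyNA(match(cladeTaxa, tree$tip.label)))
    stop("clade names unknown taxa: ",
         paste(setdiff(cladeTaxa, tree$tip.label), collapse = ", "))
  changes <- unambiguousChanges(tree, x)
  po <- attr(changes, "tree")
  ntip <- length(po$tip.label)
  E <- po$edge
  nNodes <- ntip + po$Nnode
  tipsBelow <- vector("list", nNodes)
  for (v in seq_len(ntip)) tipsBelow[[v]] <- po$tip.label[v]
  for (e in seq_len(nrow(E)))
    tipsBelow[[E[e, 1]]] <- c(tipsBelow[[E[e, 1]]], tipsBelow[[E[e, 2]]])
  if (setequal(cladeTaxa, po$tip.label)) {
    return(new("CladeSupport", clade = as.character(cladeTaxa),
               foundMonophyletic = TRUE, changes = .emptyChanges(),
               rendered = character()))
  }
  node <- NA_integer_
  for (v in seq_len(nNodes))
    if (setequal(tipsBelow[[v]], cladeTaxa)) { node <- v; break }
  if (is.na(node)) {
    return(new("CladeSupport", clade = as.character(cladeTaxa),
               foundMonophyletic = FALSE, changes = .emptyChanges(),
               rendered = character()))
  }
  sel <- changes$child == node
  sub <- changes[sel, , drop = FALSE]
  if (nrow(sub)) sub <- classifyApomorphies(sub, tree, x)
  else sub$apo_class <- character(0)
  rownames(sub) <- NULL
  new("CladeSupport", clade = as.character(cladeTaxa),
      foundMonophyletic = TRUE, changes = sub,
      rendered = if (nrow(sub))
        sprintf("%d:%d [%s]", sub$char_index, sub$to, sub$apo_class)
      else character())
}

setMethod("show", "CladeSupport", function(object) {
  cat("CladeSupport:", length(object@clade), "taxa; monophyletic:",
      object@foundMonophyletic, "\n")
  if (length(object@rendered))
    cat(" ", paste(object@rendered, collapse = "  "), "\n")
})

#' Collapse branches with no unambiguous change
#'
#' Optional post-pass producing the conservatively collapsed form of a
#' binary tree: internal branches carrying no unambiguous change for any
#' character (minimum possible branch length zero) are removed.
#'
#' @param tree rooted `phylo`.
#' @param x a [CharacterMatrix-class].
#' @return a possibly non-binary rooted `phylo`.
#' @export
collapseZeroLength <- function(tree, x) {
  tb <- .mprTables(tree, x)
  E <- tb$edge
  po <- tb$tree
  keep <- rep(FALSE, nrow(E))
  internal <- E[, 2] > tb$ntip & E[, 1] != tb$root
  for (e in which(internal)) {
    for (ch in seq_len(nCharacters(x))) {
      if (tb$tables[[ch]]$best == 0) next
      P <- .optPairs(tb, ch, e)
      idx <- which(P, arr.ind = TRUE)
      if (!any(idx[, 1] == idx[, 2])) { keep[e] <- TRUE; break }
    }
  }
  po$edge.length <- ifelse(internal & !keep, 0, 1)
  out <- ape::di2multi(po, tol = 0.5)
  out$edge.length <- NULL
  out
}

#' Paper-style apomorphy report
#'
#' Renders, per clade, the unambiguous changes on its subtending branch as
#' "index:state" plus class lines.
#'
#' @param tree rooted `phylo`.
#' @param x a [CharacterMatrix-class].
#' @param clades named list of taxon-label vectors.
#' @return character vector of report lines (one block per clade).
#' @export
apomorphyReport <- function(tree, x, clades) {
  lines <- character()
  for (nm in names(clades)) {
    cs <- cladeSupport(tree, x, clades[[nm]])
    lines <- c(lines,
               sprintf("%s (%d taxa): %s", nm, length(clades[[nm]]),
                       if (cs@foundMonophyletic) "monophyletic"
                       else "not monophyletic"))
    if (length(cs@rendered))
      lines <- c(lines, paste0("  ", cs@rendered))
  }
  lines
}
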