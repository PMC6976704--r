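# Heuristic tree search: random addition sequences + TBR branch swapping,
# under equal weights or implied weighting.

#' Create a search configuration
#'
#' @param objective `"implied_weighting"` (maximize total fit, the default)
#'   or `"equal_weights"` (minimize tree length).
#' @param k concavity constant (used under implied weighting; default 4).
#' @param replicates number of random-addition + TBR replicates (default 20;
#'   published analyses typically use many more, e.g. 1000).
#' @param treesPerReplicate buffer cap for equal-score trees per replicate.
#' @param seed master seed; every stochastic step derives from it.
#' @param maxSwaps safety cap on accepted rearrangements per replicate.
#' @return a [SearchConfig-class]
#' @export
searchConfig <- function(objective = c("implied_weighting", "equal_weights"),
                         k = 4, replicates = 20L, treesPerReplicate = 10L,
                         seed = 1L, maxSwaps = Inf) {
  objective <- match.arg(objective)
  new("SearchConfig", objective = objective, k = as.numeric(k),
      replicates = as.integer(replicates),
      treesPerReplicate = as.integer(treesPerReplicate),
      seed = as.integer(seed), maxSwaps = as.numeric(maxSwaps))
}

.objCode <- function(config) if (config@objective == "implied_weighting") 1L else 0L

# engine score (maximized) -> user scale (fit, or positive length)
.userScore <- function(score, config) {
  if (config@objective == "implied_weighting") score else -score
}

.phyloFromEngine <- function(nwk, labels) {
  tr <- ape::read.tree(text = nwk)
  tr$tip.label <- labels[as.integer(tr$tip.label)]
  tr
}

# canonical topology key over a fixed reference label order
.topoKey <- function(tree, refLabels) {
  n <- length(tree$tip.label)
  map <- match(tree$tip.label, refLabels)
  e <- tree$edge
  tipish <- e <= n
  e[tipish] <- map[e[tipish]]
  cpp_topo_key(e, length(refLabels))
}

#' Build a random-addition starting tree
#'
#' Stepwise addition: taxa are inserted in a random order, each at the edge
#' that is locally optimal under the configured objective (first edge in a
#' deterministic enumeration order on ties).  Uses the R random number
#' generator: seed it (or pass `seed`) for reproducibility.
#'
#' @param x a [CharacterMatrix-class] with at least 3 taxa.
#' @param config a [SearchConfig-class].
#' @param seed optional convenience seed applied before drawing the order.
#' @return an unrooted binary `phylo`.
#' @export
randomAdditionTree <- function(x, config = searchConfig(), seed = NULL) {
  if (nTaxa(x) < 3L) stop("need at least 3 taxa")
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(nTaxa(x))
  masks <- .engineMasks(x)
  nwk <- cpp_addition_tree(ord, masks, as.numeric(minSteps(x)),
                           config@k, .objCode(config))
  .phyloFromEngine(nwk, taxonLabels(x))
}

#' TBR branch swapping from a starting tree
#'
#' Hill-climbs over the full tree-bisection-reconnection neighborhood (every
#' edge is bisected; the two fragments are rejoined across every pair of
#' their edges) accepting the first improving rearrangement in a
#' deterministic enumeration order, until no neighbor improves the
#' objective.  Distinct equal-score neighbors of the final tree are
#' collected into the tree buffer (up to `treesPerReplicate`; overflow is
#' recorded in the log, not an error).
#'
#' @param start starting `phylo` over the matrix taxa.
#' @param x a [CharacterMatrix-class].
#' @param config a [SearchConfig-class].
#' @return a [SearchResult-class]
#' @export
tbrSearch <- function(start, x, config = searchConfig()) {
  start <- .treeForEngine(start, x)
  if (length(start$tip.label) != nTaxa(x))
    stop("start tree must carry every matrix taxon")
  labels <- taxonLabels(x)
  masks <- .engineMasks(x, taxa = labels)
  perm <- match(labels, start$tip.label)
  # renumber tips into matrix order so topology keys are comparable
  e <- start$edge
  tipish <- e <= nTaxa(x)
  e[tipish] <- match(start$tip.label, labels)[e[tipish]]
  startScore <- .userScore(.engineScoreTree(e, x, masks, config), config)
  res <- cpp_tbr(e, nTaxa(x), masks, as.numeric(minSteps(x)), config@k,
                 .objCode(config), config@treesPerReplicate,
                 config@maxSwaps)
  trees <- c(list(.phyloFromEngine(res$newick, labels)),
             lapply(res$equal, .phyloFromEngine, labels = labels))
  trees <- trees[!duplicated(vapply(trees, .topoKey, "", refLabels = labels))]
  if (length(trees) > config@treesPerReplicate)
    trees <- trees[seq_len(config@treesPerReplicate)]
  class(trees) <- "multiPhylo"
  log <- data.frame(replicate = 1L, seed = NA_integer_,
                    start_score = startScore,
                    end_score = .userScore(res$score, config),
                    swaps = res$moves, trees_kept = length(trees),
                    truncated = res$truncated)
  new("SearchResult", bestScore = .userScore(res$score, config),
      bestTrees = trees, log = log, config = config)
}

.engineScoreTree <- function(edge, x, masks, config) {
  counts <- cpp_fitch_counts(edge, nTaxa(x), masks)
  if (config@objective == "implied_weighting") {
    es <- pmax(counts - minSteps(x), 0)
    sum(config@k / (config@k + es))
  } else {
    -sum(counts)
  }
}

#' Run a multi-replicate heuristic search
#'
#' The "traditional search" strategy: `replicates` independent
#' random-addition starting trees, each refined by TBR branch swapping;
#' results are merged and deduplicated by unrooted topology.  Fully
#' deterministic given the master seed.
#'
#' @param x a [CharacterMatrix-class].
#' @param config a [SearchConfig-class].
#' @return a [SearchResult-class]
#' @examples
#' sim <- simulateMatrix(simConfig(nTaxa = 8, nChars = 40, seed = 7))
#' res <- runSearch(sim@matrix, searchConfig(replicates = 3, seed = 1))
#' res
#' @export
runSearch <- function(x, config = searchConfig()) {
  labels <- taxonLabels(x)
  set.seed(config@seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, config@replicates)
  best <- -Inf
  trees <- list()
  keys <- character()
  logs <- vector("list", config@replicates)
  for (r in seq_len(config@replicates)) {
    set.seed(repSeeds[r])
    start <- randomAdditionTree(x, config)
    res <- tbrSearch(start, x, config)
    engineScore <- if (config@objective == "implied_weighting")
      res@bestScore else -res@bestScore
    logs[[r]] <- transform(res@log, replicate = r, seed = repSeeds[r])
    if (engineScore > best + 1e-9) {
      best <- engineScore
      trees <- list()
      keys <- character()
    }
    if (engineScore >= best - 1e-9) {
      for (tr in res@bestTrees) {
        key <- .topoKey(tr, labels)
        if (!key %in% keys) {
          keys <- c(keys, key)
          trees <- c(trees, list(tr))
        }
      }
    }
  }
  class(trees) <- "multiPhylo"
  new("SearchResult",
      bestScore = .userScore(best, config),
      bestTrees = trees, log = do.call(rbind, logs), config = config)
}

setMethod("show", "SearchResult", function(object) {
  what <- if (object@config@objective == "implied_weighting")
    sprintf("total fit (k = %g)", object@config@k) else "tree length"
  cat("SearchResult:", length(object@bestTrees), "best tree(s),",
      what, "=", format(object@bestScore, digits = 10), "\n")
  cat("  replicates:", nrow(object@log), " accepted swaps:",
      sum(object@log$swaps), "\n")
})

#' Strict consensus of a set of trees
#'
#' Retains exactly the bipartitions present in every input tree; the result
#' may be non-binary (a star tree when nothing is shared).
#'
#' @param trees a `multiPhylo` or list of `phylo` over one leaf set.
#' @return a `phylo`.
#' @export
strictConsensus <- function(trees) {
  if (inherits(trees, "phylo")) return(trees)
  trees <- unclass(trees)
  sets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(sets, identical, TRUE, y = sets[[1]])))
    stop("trees do not share one leaf set")
  if (length(trees) == 1L) return(trees[[1]])
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1, rooted = FALSE)
}

#' Robinson-Foulds distance
#'
#' Symmetric-difference count of internal bipartitions between two unrooted
#' trees on the same leaf set (maximum `2(n-3)` for binary trees).
#'
#' @param a,b `phylo` objects with identical leaf sets.
#' @return integer distance.
#' @export
rfDistance <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    stop("trees do not share one leaf set: ",
         paste(c(setdiff(a$tip.label, b$tip.label),
                 setdiff(b$tip.label, a$tip.label)), collapse = ", "))
  ua <- if (ape::is.rooted(a)) ape::unroot(a) else a
  ub <- if (ape::is.rooted(b)) ape::unroot(b) else b
  as.integer(ape::dist.topo(ua, ub, method = "PH85"))
}

#' All TBR neighbors of a tree
#'
#' Enumerates every topology reachable by one bisection-reconnection move
#' (the starting topology itself is excluded; duplicates are removed).
#' Mostly useful for small-instance verification.
#'
#' @param tree an unrooted binary `phylo`.
#' @return a `multiPhylo`.
#' @export
tbrNeighbors <- function(tree) {
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2L)
    tree <- ape::unroot(tree)
  nwks <- cpp_tbr_neighbors(tree$edge, length(tree$tip.label))
  out <- lapply(nwks, .phyloFromEngine, labels = tree$tip.label)
  class(out) <- "multiPhylo"
  out
}
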