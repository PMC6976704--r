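# Fitch optimization of unordered multistate characters and the
# implied-weighting fit function.

# tree checks + conversion to the engine's (edge matrix, tip order) form
.treeForEngine <- function(tree, x) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$tip.label)) stop("tree has no tip labels")
  if (anyNA(match(tree$tip.label, taxonLabels(x))))
    stop("tree leaves absent from matrix: ",
         paste(setdiff(tree$tip.label, taxonLabels(x)), collapse = ", "))
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2L)
    tree <- ape::unroot(tree)
  tree
}

#' Fitch step count for one character
#'
#' Minimum number of state changes required by character `char` on `tree`
#' under unordered (Fitch) parsimony.  Missing and inapplicable cells enter
#' as full ambiguity over the character's defined states; polymorphic cells
#' as their state sets.  The count is invariant under the choice of root.
#'
#' @param tree `phylo`; its leaves must be a subset of the matrix taxa.
#' @param x a [CharacterMatrix-class].
#' @param char 1-based character index.
#' @return integer number of steps.
#' @export
fitchSteps <- function(tree, x, char) {
  char <- as.integer(char)
  if (char < 1L || char > nCharacters(x))
    stop("character index out of range: ", char)
  as.integer(characterSteps(tree, x)[char])
}

#' Per-character Fitch step counts
#'
#' @inheritParams fitchSteps
#' @return integer vector of length `nCharacters(x)`.
#' @export
characterSteps <- function(tree, x) {
  tree <- .treeForEngine(tree, x)
  masks <- .engineMasks(x, taxa = tree$tip.label)
  as.integer(cpp_fitch_counts(tree$edge, length(tree$tip.label), masks))
}

#' Parsimony tree length
#'
#' Sum of per-character Fitch steps.
#'
#' @inheritParams fitchSteps
#' @return integer total length.
#' @export
treeLength <- function(tree, x) {
  sum(characterSteps(tree, x))
}

#' Data minimum steps of a character
#'
#' `m = max(0, u - 1)` where `u` is the number of distinct states observed
#' in at least one single-state (unambiguous) cell.  Characters observed
#' only through ambiguous or missing cells give `m = 0`: an ambiguous cell
#' never forces a state, so extra steps `s - m` stay non-negative on every
#' tree.
#'
#' @param x a [CharacterMatrix-class]
#' @param char optional 1-based index; when missing, all characters.
#' @return integer vector of minima.
#' @export
minSteps <- function(x, char = NULL) {
  pow2 <- bitwShiftL(1L, 0:7)
  m <- vapply(seq_len(nCharacters(x)), function(j) {
    cells <- x@stateMask[x@cellKind[, j] == "observed", j]
    single <- cells[cells %in% pow2]
    max(0L, length(unique(single)) - 1L)
  }, integer(1))
  if (is.null(char)) m else m[as.integer(char)]
}

#' Implied-weighting fit of a tree
#'
#' Scores every character on the tree and sums the concave Goloboff fit
#' `f = k/(k + es)` with `es = s - m` (extra steps beyond the data minimum).
#' A homoplasy-free tree has fit exactly `nCharacters(x)`; the complement
#' `nchar - fit = sum(es/(es+k))` is reported alongside since some programs
#' display that minimized quantity instead.  The fit restricted to
#' parsimony-informative characters is also reported
#' (`informativeFit`): uninformative characters contribute exactly 1 on
#' every tree, and several optimization programs omit them from the printed
#' total.
#'
#' @inheritParams fitchSteps
#' @param k concavity constant, `k > 0`.
#' @return a [ScoreReport-class].
#' @examples
#' m <- loadPackagedMatrix()
#' cfg <- searchConfig(replicates = 1, seed = 1)
#' tr <- randomAdditionTree(m, cfg)
#' iwFit(tr, m, k = 4)
#' @export
iwFit <- function(tree, x, k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("k must be a positive real")
  s <- characterSteps(tree, x)
  # when the tree covers only part of the taxa, measure homoplasy against
  # the data minimum of the induced sub-matrix
  xs <- if (length(tree$tip.label) == nTaxa(x)) x else
    x[match(tree$tip.label, taxonLabels(x)), ]
  m <- minSteps(xs)
  es <- s - m
  if (any(es < 0)) stop("internal error: negative extra steps")
  f <- k / (k + es)
  inf <- isInformative(x)
  tab <- data.frame(char_index = seq_along(s), steps = s, min_steps = m,
                    extra_steps = es, fit = f, informative = inf)
  new("ScoreReport", scores = tab, totalFit = sum(f),
      totalLength = sum(s), complement = length(s) - sum(f),
      informativeFit = sum(f[inf]), k = k)
}

#' Parsimony-informative characters
#'
#' A character can exhibit homoplasy on some tree (extra steps > 0) only
#' when at least two of its states are each observed unambiguously in two
#' or more taxa; otherwise its extra steps are zero on every tree and its
#' fit contribution is constant.
#'
#' @param x a [CharacterMatrix-class]
#' @return logical vector over characters.
#' @export
isInformative <- function(x) {
  pow2 <- bitwShiftL(1L, 0:7)
  vapply(seq_len(nCharacters(x)), function(j) {
    cells <- x@stateMask[x@cellKind[, j] == "observed", j]
    single <- cells[cells %in% pow2]
    sum(table(single) >= 2L) >= 2L
  }, logical(1))
}

setMethod("show", "ScoreReport", function(object) {
  cat(sprintf("ScoreReport (k = %g): %d characters\n", object@k,
              nrow(object@scores)))
  cat(sprintf("  total fit        : %.4f\n", object@totalFit))
  cat(sprintf("  informative fit  : %.4f  (%d informative characters)\n",
              object@informativeFit, sum(object@scores$informative)))
  cat(sprintf("  complement       : %.4f  (nchar - fit)\n",
              object@complement))
  cat(sprintf("  tree length      : %d steps\n",
              as.integer(object@totalLength)))
})

#' Write a per-character score report as TSV
#'
#' One row per character (index, steps, data minimum, extra steps, fit) and
#' a trailing totals line.
#'
#' @param report a [ScoreReport-class]
#' @param path output file
#' @export
writeScoreReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(report@scores, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sprintf("total\t%d\t\t\t%.6f", as.integer(report@totalLength),
                     report@totalFit), con)
  invisible(path)
}
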