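#' @import methods
NULL

.PARTITIONS <- c("adult_body", "male_terminalia", "female_terminalia", "larva")
.CELL_KINDS <- c("observed", "missing", "inapplicable")

#' Discrete morphological character matrix
#'
#' Container for a taxa-by-characters grid of discrete cells.  Each cell is
#' either an observed (possibly polymorphic) set of states, an unknown entry
#' (`"?"`), or an inapplicable entry (`"-"`).  Observed state sets are stored
#' as integer bitmasks (bit *s* set means state *s* is present in the cell's
#' set); missing and inapplicable cells carry a zero mask and are told apart
#' by the `cellKind` slot.
#'
#' @slot taxa data.frame with columns `label` (unique taxon names),
#'   `ingroup` (logical) and `source_note` (free text).
#' @slot characters data.frame with columns `index` (1-based, contiguous),
#'   `partition` (one of adult_body / male_terminalia / female_terminalia /
#'   larva, or `NA` when unknown), `n_states` (number of defined states,
#'   coded contiguously from 0) and `description`.
#' @slot stateMask integer matrix (taxa x characters) of state bitmasks.
#' @slot cellKind character matrix of "observed", "missing", "inapplicable".
#'
#' @seealso [readTNT()], [readNexus()], [loadPackagedMatrix()],
#'   [validateMatrix()]
#' @export
setClass("CharacterMatrix",
  representation(
    taxa = "data.frame",
    characters = "data.frame",
    stateMask = "matrix",
    cellKind = "matrix"
  )
)

setValidity("CharacterMatrix", function(object) {
  msg <- character()
  nt <- nrow(object@taxa)
  nc <- nrow(object@characters)
  if (!identical(dim(object@stateMask), c(nt, nc)))
    msg <- c(msg, "stateMask dimensions do not match taxa x characters")
  if (!identical(dim(object@cellKind), c(nt, nc)))
    msg <- c(msg, "cellKind dimensions do not match taxa x characters")
  if (anyDuplicated(object@taxa$label))
    msg <- c(msg, "duplicated taxon labels")
  if (!identical(as.integer(object@characters$index), seq_len(nc)))
    msg <- c(msg, "character indices must be the contiguous sequence 1..N")
  bad <- !(object@characters$partition %in% .PARTITIONS) &
    !is.na(object@characters$partition)
  if (any(bad)) msg <- c(msg, "unknown character partition")
  if (length(msg)) return(msg)
  if (nt * nc > 0) {
    if (!all(object@cellKind %in% .CELL_KINDS))
      return("cellKind entries must be observed/missing/inapplicable")
    obs <- object@cellKind == "observed"
    if (any(object@stateMask[obs] <= 0L))
      return("observed cells must have a non-empty state set")
    if (any(object@stateMask[!obs] != 0L))
      return("missing/inapplicable cells must carry an empty state set")
    lim <- matrix(bitwShiftL(1L, object@characters$n_states) - 1L,
                  nt, nc, byrow = TRUE)
    if (any(bitwAnd(object@stateMask, bitwNot(lim) ) != 0L))
      return("cell references a state outside the character's defined states")
  }
  TRUE
})

#' Heuristic search configuration
#'
#' @slot objective "implied_weighting" (maximize total fit k/(k+es)) or
#'   "equal_weights" (minimize tree length).
#' @slot k concavity constant of the implied-weighting fit function.
#' @slot replicates number of random-addition + TBR replicates.
#' @slot treesPerReplicate cap on equal-score trees kept per replicate.
#' @slot seed master RNG seed.
#' @slot maxSwaps safety cap on accepted rearrangements per replicate.
#' @export
setClass("SearchConfig",
  representation(
    objective = "character",
    k = "numeric",
    replicates = "integer",
    treesPerReplicate = "integer",
    seed = "integer",
    maxSwaps = "numeric"
  )
)

setValidity("SearchConfig", function(object) {
  if (!object@objective %in% c("implied_weighting", "equal_weights"))
    return("objective must be implied_weighting or equal_weights")
  if (object@objective == "implied_weighting" &&
      (length(object@k) != 1L || !is.finite(object@k) || object@k <= 0))
    return("k must be a positive real under implied weighting")
  if (object@replicates < 1L) return("replicates must be >= 1")
  if (object@treesPerReplicate < 1L) return("treesPerReplicate must be >= 1")
  TRUE
})

#' Result of a heuristic parsimony search
#'
#' @slot bestScore total implied-weighting fit (maximized) or tree length
#'   (minimized), depending on the objective.
#' @slot bestTrees `multiPhylo` of distinct unrooted topologies attaining
#'   `bestScore`.
#' @slot log per-replicate data.frame (seed, start/end score, swaps, kept).
#' @slot config the [SearchConfig-class] used.
#' @export
setClass("SearchResult",
  representation(
    bestScore = "numeric",
    bestTrees = "ANY",
    log = "data.frame",
    config = "SearchConfig"
  )
)

#' Per-character parsimony score report
#'
#' One row per character: steps `s` on the tree, data minimum `m`, extra
#' steps `es = s - m`, and fit contribution `k/(k+es)`.
#'
#' @slot scores data.frame (char_index, steps, min_steps, extra_steps, fit).
#' @slot totalFit sum of fit contributions (the maximized quantity).
#' @slot totalLength sum of steps.
#' @slot complement `nchar - totalFit`, i.e. the minimized total
#'   `sum(es/(es+k))` some programs display instead of the fit.
#' @slot informativeFit fit summed over parsimony-informative characters
#'   only (the convention of programs that drop uninformative characters,
#'   whose fit is exactly 1 on every tree, from the printed total).
#' @slot k concavity constant.
#' @export
setClass("ScoreReport",
  representation(
    scores = "data.frame",
    totalFit = "numeric",
    totalLength = "numeric",
    complement = "numeric",
    informativeFit = "numeric",
    k = "numeric"
  )
)

#' Simulation configuration for character evolution on a random topology
#'
#' @slot nTaxa number of terminals (>= 4).
#' @slot nChars number of characters.
#' @slot nStates number of states per character (2-5).
#' @slot changeRate expected number of change events per character per tree.
#' @slot missingRate,inapplicableRate per-cell masking probabilities; their
#'   sum must be < 1.
#' @slot seed RNG seed.
#' @export
setClass("SimConfig",
  representation(
    nTaxa = "integer",
    nChars = "integer",
    nStates = "integer",
    changeRate = "numeric",
    missingRate = "numeric",
    inapplicableRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  if (object@nTaxa < 4L) return("nTaxa must be >= 4")
  if (object@nChars < 1L) return("nChars must be >= 1")
  if (object@nStates < 2L || object@nStates > 5L)
    return("nStates must be in 2..5")
  if (object@changeRate < 0) return("changeRate must be >= 0")
  if (object@missingRate < 0 || object@inapplicableRate < 0 ||
      object@missingRate + object@inapplicableRate >= 1)
    return("masking rates must be in [0,1) and sum to < 1")
  TRUE
})

#' Result of a simulation run
#'
#' @slot trueTree generating topology (`phylo`, unrooted).
#' @slot matrix simulated [CharacterMatrix-class] (after masking).
#' @slot trueChanges data.frame of generating change events
#'   (parent, child, char_index, from, to) on the tree rooted at the
#'   first taxon's pendant edge.
#' @export
setClass("SimResult",
  representation(
    trueTree = "ANY",
    matrix = "CharacterMatrix",
    trueChanges = "data.frame"
  )
)

#' Apomorphy support of a clade
#'
#' @slot clade taxon labels queried.
#' @slot foundMonophyletic whether the taxa form an exact clade on the tree.
#' @slot changes data.frame of unambiguous changes on the subtending branch
#'   (with global/local classification).
#' @slot rendered the "index:state" strings with their class in brackets.
#' @export
setClass("CladeSupport",
  representation(
    clade = "character",
    foundMonophyletic = "logical",
    changes = "data.frame",
    rendered = "character"
  )
)
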