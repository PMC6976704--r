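# Simulation of unordered multistate characters on a random topology, with
# controllable homoplasy (expected change events per character), missing-
# and inapplicable-data rates.  An event-on-branch (jump) process is used
# rather than a rate-matrix model: parsimony is the inference target, and
# the generating change events themselves are needed to test the
# apomorphy-mapping stage.

#' Create a simulation configuration
#'
#' @param nTaxa number of terminals (>= 4).
#' @param nChars number of characters.
#' @param nStates states per character (2-5; coded 0..nStates-1).
#' @param changeRate expected number of change events per character on the
#'   whole tree (events are Poisson over the tree, placed uniformly across
#'   branches; each event moves to a uniformly chosen different state).
#' @param missingRate,inapplicableRate independent per-cell masking
#'   probabilities (sum < 1).
#' @param seed RNG seed; the whole simulation is a pure function of it.
#' @return a [SimConfig-class]
#' @export
simConfig <- function(nTaxa, nChars, nStates = 2L, changeRate = 1,
                      missingRate = 0, inapplicableRate = 0, seed = 1L) {
  new("SimConfig", nTaxa = as.integer(nTaxa), nChars = as.integer(nChars),
      nStates = as.integer(nStates), changeRate = as.numeric(changeRate),
      missingRate = as.numeric(missingRate),
      inapplicableRate = as.numeric(inapplicableRate),
      seed = as.integer(seed))
}

#' Simulate a character matrix on a random topology
#'
#' Samples a uniform random unrooted binary topology, evolves each
#' character along it under the jump process described in [simConfig()],
#' then masks cells to missing / inapplicable at the configured rates.
#' The generating topology and the true change events (recorded on the tree
#' rooted at the first taxon's pendant edge) are returned with the matrix.
#'
#' @param config a [SimConfig-class]
#' @return a [SimResult-class]
#' @examples
#' sim <- simulateMatrix(simConfig(nTaxa = 8, nChars = 50, seed = 42))
#' sim@trueTree; sim@matrix
#' @export
simulateMatrix <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nTaxa
  labels <- sprintf("t%02d", seq_len(n))
  tree <- ape::rtopology(n, rooted = FALSE, tip.label = labels)
  tree$edge.length <- NULL
  rt <- rootOnOutgroup(tree, labels[1])
  po <- ape::reorder.phylo(rt, "postorder")
  E <- po$edge
  nNodes <- length(po$tip.label) + po$Nnode
  root <- E[nrow(E), 1]
  preorder <- rev(seq_len(nrow(E)))
  S <- config@nStates
  tokens <- matrix("", n, config@nChars)
  events <- list()
  for (ch in seq_len(config@nChars)) {
    nev <- stats::rpois(1, config@changeRate)
    onEdge <- if (nev > 0) sample.int(nrow(E), nev, replace = TRUE) else integer()
    state <- integer(nNodes)
    state[root] <- sample.int(S, 1) - 1L
    for (e in preorder) {
      st <- state[E[e, 1]]
      for (k in seq_len(sum(onEdge == e))) {
        new_st <- sample(setdiff(0:(S - 1), st), 1)
        events[[length(events) + 1L]] <- data.frame(
          parent = E[e, 1], child = E[e, 2], char_index = ch,
          from = st, to = new_st, stringsAsFactors = FALSE)
        st <- new_st
      }
      state[E[e, 2]] <- st
    }
    tokens[, ch] <- as.character(state[seq_len(n)])
  }
  # masking
  if (config@missingRate + config@inapplicableRate > 0) {
    u <- matrix(stats::runif(n * config@nChars), n, config@nChars)
    tokens[u < config@missingRate] <- "?"
    tokens[u >= config@missingRate &
             u < config@missingRate + config@inapplicableRate] <- "-"
  }
  chars <- data.frame(index = seq_len(config@nChars),
                      partition = NA_character_, n_states = S,
                      description = paste("simulated character",
                                          seq_len(config@nChars)),
                      stringsAsFactors = FALSE)
  mat <- characterMatrix(tokens, data.frame(label = labels), chars)
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(parent = integer(), child = integer(), char_index = integer(),
               from = integer(), to = integer())
  new("SimResult", trueTree = tree, matrix = mat, trueChanges = ev)
}

setMethod("show", "SimResult", function(object) {
  cat("SimResult:", nTaxa(object@matrix), "taxa x",
      nCharacters(object@matrix), "characters;",
      nrow(object@trueChanges), "generating change events\n")
})

#' Hand-built miniature instances
#'
#' Small (<= 8 taxa) matrix/tree pairs for exercising every pipeline stage;
#' expected lengths, fits and change sets are meant to be recomputed by
#' exhaustive oracles at test time, not hard-coded here.
#'
#' @return list of lists with elements `matrix`, `tree`, `note`.
#' @export
fixtureMiniatures <- function() {
  mk <- function(tokens, labels, nwk, note) {
    list(matrix = characterMatrix(tokens, data.frame(label = labels)),
         tree = ape::read.tree(text = nwk), note = note)
  }
  list(
    mk(matrix(c("0", "0", "1", "1"), 4, 1), c("A", "B", "C", "D"),
       "((A,B),(C,D));", "single binary character, one synapomorphy"),
    mk(cbind(c("0", "1", "1", "1", "1"),
             c("0", "0", "1", "1", "1"),
             c("0", "0", "0", "1", "1")),
       c("A", "B", "C", "D", "E"),
       "(A,(B,(C,(D,E))));", "homoplasy-free nested characters"),
    mk(cbind(c("0", "0", "1", "0", "1", "0"),
             c("0", "0", "1", "1", "1", "1"),
             c("0", "1", "?", "0", "-", "1")),
       c("A", "B", "C", "D", "E", "F"),
       "((A,B),((C,D),(E,F)));",
       "first character convergent (C and E), third with missing/inapplicable")
  )
}
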