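# Construction helpers and accessors for CharacterMatrix.

.tokenKind <- function(tok) {
  ifelse(tok == "?", "missing", ifelse(tok %in% c("-", "–"), "inapplicable", "observed"))
}

.tokenMask <- function(tok) {
  # "0".."9", "[01]", "{01}" or "0/1" -> bitmask; "?"/"-" -> 0
  if (tok == "?" || tok %in% c("-", "–")) return(0L)
  dig <- strsplit(gsub("[^0-9]", "", tok), "")[[1]]
  if (!length(dig)) stop("unparseable cell token: '", tok, "'")
  m <- 0L
  for (d in as.integer(dig)) m <- bitwOr(m, bitwShiftL(1L, d))
  m
}

#' Build a CharacterMatrix from cell tokens
#'
#' Low-level constructor used by the readers and the simulator.  `tokens` is
#' a character matrix whose entries are single states (`"0"`), polymorphism
#' groups (`"[01]"`, `"{01}"`, `"0/1"`), `"?"` (missing) or `"-"`
#' (inapplicable).
#'
#' @param tokens character matrix (taxa in rows).
#' @param taxa data.frame with columns label, ingroup, source_note (label
#'   alone is enough; the rest defaults).
#' @param characters optional data.frame (index, partition, n_states,
#'   description); when absent, state counts are inferred from the observed
#'   cells and partitions are `NA`.
#' @return a validated [CharacterMatrix-class].
#' @export
characterMatrix <- function(tokens, taxa, characters = NULL) {
  tokens <- as.matrix(tokens)
  if (is.character(taxa)) taxa <- data.frame(label = taxa)
  if (is.null(taxa$ingroup)) taxa$ingroup <- TRUE
  if (is.null(taxa$source_note)) taxa$source_note <- ""
  taxa <- data.frame(label = as.character(taxa$label),
                     ingroup = as.logical(taxa$ingroup),
                     source_note = as.character(taxa$source_note),
                     stringsAsFactors = FALSE)
  nt <- nrow(tokens); nc <- ncol(tokens)
  mask <- matrix(0L, nt, nc)
  for (i in seq_len(nt)) for (j in seq_len(nc))
    mask[i, j] <- .tokenMask(tokens[i, j])
  kind <- matrix(.tokenKind(tokens), nt, nc)
  if (is.null(characters)) {
    nst <- vapply(seq_len(nc), function(j) {
      mx <- 0L
      for (b in 0:7) if (any(bitwAnd(mask[, j], bitwShiftL(1L, b)) != 0L))
        mx <- b + 1L
      max(mx, 1L)
    }, integer(1))
    characters <- data.frame(index = seq_len(nc), partition = NA_character_,
                             n_states = nst,
                             description = paste("character", seq_len(nc)),
                             stringsAsFactors = FALSE)
  }
  characters$index <- as.integer(characters$index)
  characters$n_states <- as.integer(characters$n_states)
  rownames(mask) <- rownames(kind) <- taxa$label
  new("CharacterMatrix", taxa = taxa, characters = characters,
      stateMask = mask, cellKind = kind)
}

#' @describeIn characterMatrix number of taxa
#' @param x a `CharacterMatrix`
#' @export
nTaxa <- function(x) nrow(x@taxa)

#' @describeIn characterMatrix number of characters
#' @export
nCharacters <- function(x) nrow(x@characters)

#' @describeIn characterMatrix taxon labels, in matrix order
#' @export
taxonLabels <- function(x) x@taxa$label

#' @describeIn characterMatrix logical ingroup flag per taxon
#' @export
isIngroup <- function(x) structure(x@taxa$ingroup, names = x@taxa$label)

#' @describeIn characterMatrix the per-character metadata table
#' @export
characterInfo <- function(x) x@characters

#' @describeIn characterMatrix the taxon metadata table
#' @export
taxonInfo <- function(x) x@taxa

#' Decode one cell
#'
#' @param x a [CharacterMatrix-class]
#' @param taxon taxon label or row index
#' @param char character index (1-based)
#' @return a list with `kind` and the integer vector of `states`
#'   (empty for missing/inapplicable cells).
#' @export
cellStates <- function(x, taxon, char) {
  i <- if (is.character(taxon)) match(taxon, x@taxa$label) else as.integer(taxon)
  if (is.na(i) || i < 1L || i > nTaxa(x)) stop("unknown taxon: ", taxon)
  if (char < 1L || char > nCharacters(x)) stop("character index out of range")
  m <- x@stateMask[i, char]
  states <- which(bitwAnd(m, bitwShiftL(1L, 0:7)) != 0L) - 1L
  list(kind = x@cellKind[i, char], states = as.integer(states))
}

# bitmasks with missing/inapplicable expanded to full ambiguity over the
# character's defined states -- the form the optimization engine consumes
.engineMasks <- function(x, taxa = NULL) {
  full <- bitwShiftL(1L, x@characters$n_states) - 1L
  m <- x@stateMask
  fullm <- matrix(full, nrow(m), ncol(m), byrow = TRUE)
  m[m == 0L] <- fullm[m == 0L]
  if (!is.null(taxa)) {
    idx <- match(taxa, x@taxa$label)
    if (anyNA(idx)) stop("taxa absent from matrix: ",
                         paste(taxa[is.na(idx)], collapse = ", "))
    m <- m[idx, , drop = FALSE]
  }
  storage.mode(m) <- "integer"
  m
}

# cell tokens back from the internal representation
.cellTokens <- function(x, poly = c("[", "{")) {
  open <- match.arg(poly)
  close <- if (open == "[") "]" else "}"
  nt <- nTaxa(x); nc <- nCharacters(x)
  out <- matrix("", nt, nc)
  for (i in seq_len(nt)) for (j in seq_len(nc)) {
    k <- x@cellKind[i, j]
    if (k == "missing") out[i, j] <- "?"
    else if (k == "inapplicable") out[i, j] <- "-"
    else {
      st <- which(bitwAnd(x@stateMask[i, j], bitwShiftL(1L, 0:7)) != 0L) - 1L
      out[i, j] <- if (length(st) == 1L) as.character(st) else
        paste0(open, paste(st, collapse = ""), close)
    }
  }
  out
}

#' Subset a character matrix
#'
#' `x[i, j]` restricts to taxa `i` (indices or labels) and characters `j`;
#' character indices are renumbered to stay contiguous.
#'
#' @param x a [CharacterMatrix-class]
#' @param i taxon indices or labels
#' @param j character indices
#' @param ... ignored
#' @param drop ignored (always `FALSE`)
#' @export
setMethod("[", "CharacterMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nTaxa(x))
  if (missing(j)) j <- seq_len(nCharacters(x))
  if (is.character(i)) i <- match(i, taxonLabels(x))
  if (anyNA(i)) stop("unknown taxa in subset")
  taxa <- x@taxa[i, , drop = FALSE]
  rownames(taxa) <- NULL
  chars <- x@characters[j, , drop = FALSE]
  chars$index <- seq_len(nrow(chars))
  rownames(chars) <- NULL
  new("CharacterMatrix", taxa = taxa, characters = chars,
      stateMask = x@stateMask[i, j, drop = FALSE],
      cellKind = x@cellKind[i, j, drop = FALSE])
})

setMethod("show", "CharacterMatrix", function(object) {
  cat("CharacterMatrix:", nTaxa(object), "taxa x", nCharacters(object),
      "characters\n")
  cat("  ingroup taxa:", sum(object@taxa$ingroup), "\n")
  kinds <- table(factor(object@cellKind, levels = .CELL_KINDS))
  cat(sprintf("  cells: %d observed, %d missing, %d inapplicable\n",
              kinds[["observed"]], kinds[["missing"]],
              kinds[["inapplicable"]]))
  pt <- table(object@characters$partition, useNA = "ifany")
  cat("  partitions:", paste(names(pt), pt, sep = "=", collapse = ", "), "\n")
})

#' Structural validation of a character matrix
#'
#' Checks the data-model invariants and returns the violations as a
#' data.frame of findings; an empty result means the matrix is valid.
#' Content problems are reported, never raised.
#'
#' @param x a [CharacterMatrix-class]
#' @return data.frame with columns `taxon`, `char`, `problem`.
#' @export
validateMatrix <- function(x) {
  f <- data.frame(taxon = character(), char = integer(),
                  problem = character(), stringsAsFactors = FALSE)
  add <- function(taxon, char, problem)
    rbind(f, data.frame(taxon = taxon, char = char, problem = problem,
                        stringsAsFactors = FALSE))
  dup <- x@taxa$label[duplicated(x@taxa$label)]
  for (d in unique(dup)) f <- add(d, NA_integer_, "duplicated taxon label")
  nt <- nTaxa(x); nc <- nCharacters(x)
  if (!identical(dim(x@stateMask), c(nt, nc)) ||
      !identical(dim(x@cellKind), c(nt, nc)))
    f <- add(NA_character_, NA_integer_, "grid dimensions mismatch")
  if (!identical(as.integer(x@characters$index), seq_len(nc)))
    f <- add(NA_character_, NA_integer_, "character indices not contiguous 1..N")
  lim <- bitwShiftL(1L, x@characters$n_states) - 1L
  for (j in seq_len(nc)) {
    bad <- which(bitwAnd(x@stateMask[, j], bitwNot(lim[j])) != 0L)
    for (i in bad)
      f <- add(x@taxa$label[i], j, "state outside the character's defined states")
    obs <- x@cellKind[, j] == "observed"
    for (i in which(obs & x@stateMask[, j] == 0L))
      f <- add(x@taxa$label[i], j, "observed cell with empty state set")
    for (i in which(!obs & x@stateMask[, j] != 0L))
      f <- add(x@taxa$label[i], j, "missing/inapplicable cell with states")
  }
  f
}
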