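# Readers / writers for the two matrix dialects.
#
# No installed package parses TNT xread files, and the available NEXUS data
# readers collapse the missing ("?") vs inapplicable ("-") distinction the
# data model preserves, so both dialects get a small dedicated parser here.

# split a state string ("010[01]?-1...") into cell tokens
.splitStateString <- function(s, taxon, poly_open, poly_close) {
  chars <- strsplit(s, "")[[1]]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% poly_open) {
      cl <- poly_close[match(ch, poly_open)]
      j <- i + 1L
      grp <- character(0)
      while (j <= length(chars) && chars[j] != cl) {
        if (!grepl("[0-9]", chars[j]))
          stop("parse error: bad symbol '", chars[j], "' inside polymorphism ",
               "group, taxon '", taxon, "' position ", j)
        grp <- c(grp, chars[j]); j <- j + 1L
      }
      if (j > length(chars))
        stop("parse error: unterminated polymorphism group, taxon '", taxon, "'")
      out <- c(out, paste0("[", paste(grp, collapse = ""), "]"))
      i <- j + 1L
    } else if (grepl("[0-9]", ch) || ch %in% c("?", "-", "–")) {
      out <- c(out, if (ch == "–") "-" else ch)
      i <- i + 1L
    } else {
      stop("parse error: unknown symbol '", ch, "' for taxon '", taxon,
           "' at position ", i)
    }
  }
  out
}

.rowsToMatrix <- function(labels, strings, nchar_exp, poly_open, poly_close) {
  toks <- vector("list", length(labels))
  for (r in seq_along(labels)) {
    tk <- .splitStateString(strings[r], labels[r], poly_open, poly_close)
    if (length(tk) != nchar_exp)
      stop("parse error: taxon '", labels[r], "' (row ", r, ") has ",
           length(tk), " characters, expected ", nchar_exp)
    toks[[r]] <- tk
  }
  do.call(rbind, toks)
}

#' Read a TNT xread matrix
#'
#' Expects `xread <nchar> <ntax>` followed by one `name statestring` row per
#' taxon and a terminating `;`.  Symbols: digits 0-9 for states, `?` missing,
#' `-` inapplicable, `[..]` polymorphism.
#'
#' @param path file path
#' @param characters optional character metadata table to attach (as in
#'   [characterMatrix()]).
#' @return a [CharacterMatrix-class]
#' @export
readTNT <- function(path, characters = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  h <- grep("^xread\\b", lines)
  if (!length(h)) stop("parse error: no xread header")
  hd <- strsplit(lines[h[1]], "\\s+")[[1]]
  if (length(hd) < 3L) stop("parse error: xread header needs nchar and ntax")
  nchar_exp <- as.integer(hd[2]); ntax_exp <- as.integer(hd[3])
  body <- lines[(h[1] + 1L):length(lines)]
  body <- body[body != ";"]
  body <- sub(";\\s*$", "", body)
  body <- body[nzchar(body)]
  if (length(body) != ntax_exp)
    stop("parse error: found ", length(body), " taxon rows, header says ",
         ntax_exp)
  parts <- regmatches(body, regexpr("^\\S+", body))
  strings <- trimws(sub("^\\S+", "", body))
  toks <- .rowsToMatrix(parts, strings, nchar_exp, "[", "]")
  characterMatrix(toks, data.frame(label = parts), characters)
}

#' Read a NEXUS DATA/CHARACTERS matrix
#'
#' Honors `MISSING` and `GAP` symbols from the FORMAT line (defaults `?` and
#' `-`); both `{..}` and `[..]` polymorphism groups are accepted.
#'
#' @inheritParams readTNT
#' @return a [CharacterMatrix-class]
#' @export
readNexus <- function(path, characters = NULL) {
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  if (!grepl("#NEXUS", txt, ignore.case = TRUE))
    stop("parse error: not a NEXUS file")
  dims <- regmatches(txt, regexpr("DIMENSIONS[^;]*;", txt, ignore.case = TRUE))
  if (!length(dims)) stop("parse error: no DIMENSIONS statement")
  ntax_exp <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", dims,
                             ignore.case = TRUE))
  nchar_exp <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", dims,
                              ignore.case = TRUE))
  missing_sym <- "?"; gap_sym <- "-"
  fmt <- regmatches(txt, regexpr("FORMAT[^;]*;", txt, ignore.case = TRUE))
  if (length(fmt)) {
    mm <- regmatches(fmt, regexpr("MISSING\\s*=\\s*\\S", fmt, ignore.case = TRUE))
    if (length(mm)) missing_sym <- substring(mm, nchar(mm))
    gg <- regmatches(fmt, regexpr("GAP\\s*=\\s*\\S", fmt, ignore.case = TRUE))
    if (length(gg)) gap_sym <- substring(gg, nchar(gg))
  }
  mstart <- regexpr("MATRIX", txt, ignore.case = TRUE)
  if (mstart < 0) stop("parse error: no MATRIX keyword")
  rest <- substring(txt, mstart + attr(mstart, "match.length"))
  mend <- regexpr(";", rest, fixed = TRUE)
  if (mend < 0) stop("parse error: unterminated MATRIX block")
  rows <- strsplit(substring(rest, 1, mend - 1), "\n")[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]
  if (length(rows) != ntax_exp)
    stop("parse error: found ", length(rows), " taxon rows, DIMENSIONS says ",
         ntax_exp)
  labels <- regmatches(rows, regexpr("^\\S+", rows))
  strings <- trimws(sub("^\\S+", "", rows))
  strings <- gsub(missing_sym, "?", strings, fixed = TRUE)
  strings <- gsub(gap_sym, "-", strings, fixed = TRUE)
  toks <- .rowsToMatrix(labels, strings, nchar_exp, c("{", "["), c("}", "]"))
  characterMatrix(toks, data.frame(label = labels), characters)
}

#' Write a matrix in TNT xread format
#'
#' @param x a [CharacterMatrix-class]
#' @param path output file
#' @export
writeTNT <- function(x, path) {
  toks <- .cellTokens(x, "[")
  rows <- apply(toks, 1, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("xread %d %d", nCharacters(x), nTaxa(x)), con)
  writeLines(sprintf("%-28s %s", taxonLabels(x), rows), con)
  writeLines(";", con)
  invisible(path)
}

#' Write a matrix in NEXUS format
#'
#' Polymorphic cells are emitted as `{..}` groups; missing as `?`,
#' inapplicable as `-`.
#'
#' @inheritParams writeTNT
#' @export
writeNexus <- function(x, path) {
  toks <- .cellTokens(x, "{")
  rows <- apply(toks, 1, paste, collapse = "")
  maxstate <- max(x@characters$n_states)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nTaxa(x), nCharacters(x)),
             con)
  writeLines(sprintf('FORMAT SYMBOLS="%s" MISSING=? GAP=-;',
                     paste(0:(maxstate - 1), collapse = "")), con)
  writeLines("MATRIX", con)
  writeLines(sprintf("%-28s %s", taxonLabels(x), rows), con)
  writeLines(";", con)
  writeLines("END;", con)
  invisible(path)
}
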