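# The packaged Rhinophoridae matrix: a transcription of the published
# 68-taxon x 99-character morphological data set (57 rhinophorid terminals
# plus 11 outgroups), with its character list, partitions and named clades.

.extdata <- function(f) {
  p <- system.file("extdata", f, package = "cladiw", mustWork = TRUE)
  p
}

#' Load the packaged Rhinophoridae character matrix
#'
#' Returns the bundled 68 x 99 morphological matrix (57 ingroup woodlouse-fly
#' terminals, 11 oestroid outgroups; the first taxon, `Musca_spp`, is the
#' conventional rooting outgroup).  Characters 1-52 describe the adult body,
#' 53-81 the male terminalia, 82 the female terminalia and 83-99 the first
#' instar larva.  Cells code single states 0-4, polymorphism (state sets),
#' unknown (`?`) and inapplicable (`-`) entries.
#'
#' @return a [CharacterMatrix-class] with partitions and ingroup flags set.
#' @examples
#' m <- loadPackagedMatrix()
#' nTaxa(m); nCharacters(m); sum(isIngroup(m))
#' @export
loadPackagedMatrix <- function() {
  chars <- utils::read.delim(.extdata("rhinophoridae_characters.tsv"),
                             stringsAsFactors = FALSE)
  taxa <- utils::read.delim(.extdata("rhinophoridae_taxa.tsv"),
                            stringsAsFactors = FALSE)
  taxa$source_note[is.na(taxa$source_note)] <- ""
  x <- readTNT(.extdata("rhinophoridae_matrix.tnt"), characters = chars)
  stopifnot(identical(taxonLabels(x), taxa$label))
  x@taxa$ingroup <- taxa$ingroup
  x@taxa$source_note <- taxa$source_note
  validObject(x)
  x
}

#' Named clades of the packaged analysis
#'
#' Taxon sets for the named clades (A-I, where printed in full) and the four
#' newly erected genera, for use with [cladeSupport()].
#'
#' @return named list of taxon-label vectors.
#' @export
cladeDefinitions <- function() {
  tb <- utils::read.delim(.extdata("rhinophoridae_clades.tsv"),
                          stringsAsFactors = FALSE)
  out <- lapply(tb$taxa, function(s) strsplit(s, ",", fixed = TRUE)[[1]])
  names(out) <- tb$clade
  out
}
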