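FRAME_LABELS <- c("+1", "+2", "+3", "-1", "-2", "-3")

## translate one strand-oriented DNAStringSet in frame off+1 (off in 0:2)
translate_frame <- function(dna, off) {
  w <- Biostrings::width(dna)
  start <- pmin(off + 1L, w + 1L)
  x <- Biostrings::subseq(dna, start = start)
  w2 <- Biostrings::width(x)
  x <- Biostrings::subseq(x, end = w2 - (w2 %% 3L))
  Biostrings::translate(x, if.fuzzy.codon = "X")
}

## all six frames of a DNAStringSet -> named list of AAStringSet
six_frame_set <- function(dna) {
  rc <- Biostrings::reverseComplement(dna)
  out <- c(
    lapply(0:2, function(off) translate_frame(dna, off)),
    lapply(0:2, function(off) translate_frame(rc, off))
  )
  names(out) <- FRAME_LABELS
  out
}

#' Six-frame translation of a DNA sequence
#'
#' Translates a read in all six reading frames under the standard genetic
#' code. Frames -1..-3 are the forward frames of the reverse complement.
#' Codons containing `N` translate to `X`; stop codons are rendered `*`.
#' Trailing bases that do not complete a codon are dropped.
#'
#' @param dna a single DNA sequence (character or [Biostrings::DNAString]),
#'   alphabet `A`, `C`, `G`, `T`, `N`.
#' @return named character vector of six peptides
#'   (`"+1"`, `"+2"`, `"+3"`, `"-1"`, `"-2"`, `"-3"`).
#' @examples
#' six_frame_translate("ATGGCC")["+1"]  # "MA"
#' @export
six_frame_translate <- function(dna) {
  dna <- toupper(as.character(dna))
  if (length(dna) != 1L) stopf("six_frame_translate() expects one sequence")
  if (!grepl("^[ACGTN]*$", dna)) {
    stopf("sequence contains characters outside {A,C,G,T,N}")
  }
  if (nchar(dna) == 0L) {
    return(setNames(rep("", 6L), FRAME_LABELS))
  }
  set <- six_frame_set(Biostrings::DNAStringSet(dna))
  vapply(set, function(x) as.character(x)[1], "")
}
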