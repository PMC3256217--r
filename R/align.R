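#' Alignment scoring scheme with Karlin-Altschul statistics
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters used to convert raw Smith-Waterman scores to
#' bit scores and E-values. Defaults are the standard gapped BLASTP
#' constants for BLOSUM62 with gap open 11 / extend 1
#' (lambda = 0.267 nats per score unit, K = 0.041).
#'
#' Bit scores are `(lambda * raw - ln K) / ln 2`; E-values are
#' `m * n * 2^(-bit)` with `m` the translated query length in residues and
#' `n` the total residue count of the database searched.
#'
#' @param matrix_name name of a substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend positive gap penalties; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param lambda,K Karlin-Altschul parameters.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, lambda = 0.267, K = 0.041) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0, K < 1)
  e <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = e)
  structure(
    list(matrix_name = matrix_name, matrix = get(matrix_name, envir = e),
         gap_open = gap_open, gap_extend = gap_extend,
         lambda = lambda, K = K),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring scheme: %s, gap %g/%g, lambda %g, K %g\n",
              x$matrix_name, x$gap_open, x$gap_extend, x$lambda, x$K))
  invisible(x)
}

## raw score -> bit score
bit_from_raw <- function(raw, scheme) {
  (scheme$lambda * raw - log(scheme$K)) / log(2)
}

## bit score -> E-value in an m x n residue search space
evalue_from_bit <- function(bit, m, n) {
  m * n * 2^(-bit)
}

## split a peptide at stop codons; returns data.frame(seg, offset) where
## offset is the 0-based residue offset of the segment within the peptide.
## Alignments never cross a '*' (stop codons break alignments).
split_at_stops <- function(peptide) {
  if (!nzchar(peptide)) return(data.frame(seg = character(), offset = integer()))
  parts <- strsplit(peptide, "*", fixed = TRUE)[[1]]
  if (length(parts) == 0L) parts <- ""
  offs <- cumsum(c(0L, nchar(parts) + 1L))[seq_along(parts)]
  keep <- nzchar(parts)
  data.frame(seg = parts[keep], offset = offs[keep])
}

## batch local alignment of peptide segments against one protein.
## Returns a data.frame with raw scores and 0-based half-open intervals
## (pstart/pend on the segment, sstart/send on the subject).
align_segments <- function(segs, subject, scheme) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(segs), Biostrings::AAString(subject),
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = "local", scoreOnly = FALSE
  )
  ins <- Biostrings::nindel(pa)
  data.frame(
    raw_score = Biostrings::score(pa),
    pstart = IRanges::start(Biostrings::pattern(pa)) - 1L,
    pend   = IRanges::end(Biostrings::pattern(pa)),
    sstart = IRanges::start(Biostrings::subject(pa)) - 1L,
    send   = IRanges::end(Biostrings::subject(pa)),
    nmatch = Biostrings::nmatch(pa),
    nmismatch = Biostrings::nmismatch(pa),
    gap_openings = ins@insertion[, 1L] + ins@deletion[, 1L],
    gap_residues = ins@insertion[, 2L] + ins@deletion[, 2L]
  )
}

#' Optimal local alignment of a peptide against a protein
#'
#' Affine-gap Smith-Waterman via the Biostrings alignment engine. Stop
#' codons (`*`) in the peptide break alignments: the peptide is split at
#' stops and the best-scoring segment alignment is returned. An alignment
#' with non-positive optimal score is reported as `NULL` (no local
#' similarity).
#'
#' @param peptide query peptide (may contain `*` and `X`).
#' @param protein subject protein sequence.
#' @param scheme a [scoring_scheme()].
#' @return `NULL`, or a list with `raw_score`, `query_interval` and
#'   `subject_interval` (0-based half-open residue intervals),
#'   `alignment_length` (columns, residues), `nmatch`, `nmismatch`,
#'   `gap_openings`, `gap_residues` and `identity` (matches / columns).
#' @examples
#' local_align("MA", "MA", scoring_scheme())$raw_score  # 9
#' @export
local_align <- function(peptide, protein, scheme = scoring_scheme()) {
  stopifnot(nzchar(peptide), nzchar(protein))
  segs <- split_at_stops(peptide)
  if (nrow(segs) == 0L) return(NULL)
  res <- align_segments(segs$seg, protein, scheme)
  best <- which.max(res$raw_score)
  if (res$raw_score[best] <= 0) return(NULL)
  r <- res[best, ]
  off <- segs$offset[best]
  alen <- r$nmatch + r$nmismatch + r$gap_residues
  list(
    raw_score = r$raw_score,
    query_interval = c(off + r$pstart, off + r$pend),
    subject_interval = c(r$sstart, r$send),
    alignment_length = alen,
    nmatch = r$nmatch,
    nmismatch = r$nmismatch,
    gap_openings = r$gap_openings,
    gap_residues = r$gap_residues,
    identity = r$nmatch / alen
  )
}
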