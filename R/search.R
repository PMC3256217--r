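## Build a seed index over a protein database: every amino-acid k-mer of
## every entry, as a data.table keyed by kmer. Used to restrict the
## Smith-Waterman stage to read/protein pairs sharing at least one exact
## k-mer, the same word-seeding idea BLAST itself relies on.
build_seed_index <- function(db, k = 5L) {
  kmers <- lapply(seq_len(nrow(db)), function(i) {
    s <- db$sequence[i]
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character())
    unique(substring(s, 1:n, k:nchar(s)))
  })
  idx <- data.table::data.table(
    kmer = unlist(kmers),
    db_index = rep.int(seq_len(nrow(db)), lengths(kmers))
  )
  data.table::setkey(idx, kmer)
  list(db = db, index = idx, k = as.integer(k),
       total_residues = sum(nchar(db$sequence)))
}

## k-mers of peptide segments -> data.table(seg_index, kmer)
segment_kmers <- function(segs, k) {
  km <- lapply(segs, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character())
    unique(substring(s, 1:n, k:nchar(s)))
  })
  data.table::data.table(
    seg_index = rep.int(seq_along(segs), lengths(km)),
    kmer = unlist(km)
  )
}

## Translate every read in all six frames and split at stop codons.
## Returns data.table: read_index, frame (+1..+3,-1..-3 as integer),
## offset (0-based aa offset in the frame), seg (peptide segment), and an
## attribute qlen_res per read (longest frame translation, residues).
translated_segments <- function(reads) {
  frames <- six_frame_set(reads)
  frame_codes <- c(1L, 2L, 3L, -1L, -2L, -3L)
  pieces <- vector("list", 6L)
  qlen <- rep(0L, length(reads))
  for (f in 1:6) {
    pep <- as.character(frames[[f]])
    qlen <- pmax(qlen, nchar(pep))
    parts <- strsplit(pep, "*", fixed = TRUE)
    lens <- lengths(parts)
    ri <- rep.int(seq_along(pep), lens)
    seg <- unlist(parts, use.names = FALSE)
    off <- unlist(lapply(parts, function(p) {
      if (length(p) == 0L) return(integer())
      cumsum(c(0L, nchar(p) + 1L))[seq_along(p)]
    }), use.names = FALSE)
    keep <- nzchar(seg)
    pieces[[f]] <- data.table::data.table(
      read_index = ri[keep], frame = frame_codes[f],
      offset = off[keep], seg = seg[keep]
    )
  }
  out <- data.table::rbindlist(pieces)
  attr(out, "qlen_res") <- qlen
  out
}

## Core search: best local alignment of every read against database
## entries, with Karlin-Altschul statistics. mode "family_best" keeps the
## best hit per (read, family); "db_best" the single best hit per read.
## Hits with E > e_max are dropped. min_raw_score prunes the (many)
## trivially weak seeded alignments before statistics.
search_dataset <- function(d, index, scheme = scoring_scheme(),
                           e_max = 0.10,
                           mode = c("family_best", "db_best"),
                           use_seeds = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is(d, "mg_dataset"))
  db <- index$db
  n_db_res <- index$total_residues
  if (nrow(db) == 0L) {
    return(empty_hits())
  }
  segs <- translated_segments(d$reads)
  qlen <- attr(segs, "qlen_res")
  if (nrow(segs) == 0L) return(empty_hits())

  if (use_seeds) {
    sk <- segment_kmers(segs$seg, index$k)
    cand <- unique(index$index[sk, on = "kmer", nomatch = NULL,
                               .(seg_index, db_index)])
  } else {
    cand <- data.table::CJ(seg_index = seq_len(nrow(segs)),
                           db_index = seq_len(nrow(db)))
  }
  if (nrow(cand) == 0L) return(empty_hits())

  res <- vector("list", length(unique(cand$db_index)))
  ui <- 0L
  for (di in sort(unique(cand$db_index))) {
    si <- cand$seg_index[cand$db_index == di]
    al <- align_segments(segs$seg[si], db$sequence[di], scheme)
    ok <- which(al$raw_score > 0)
    if (length(ok) == 0L) next
    ui <- ui + 1L
    al <- al[ok, ]
    s <- segs[si[ok], ]
    res[[ui]] <- data.table::data.table(
      read_index = s$read_index, frame = s$frame,
      db_index = di,
      raw_score = al$raw_score,
      q_aa_start = s$offset + al$pstart, q_aa_end = s$offset + al$pend,
      sstart = al$sstart, send = al$send,
      nmatch = al$nmatch, nmismatch = al$nmismatch,
      gap_openings = al$gap_openings, gap_residues = al$gap_residues
    )
  }
  if (ui == 0L) return(empty_hits())
  hits <- data.table::rbindlist(res[seq_len(ui)])

  hits[, bit_score := bit_from_raw(raw_score, scheme)]
  hits[, evalue := evalue_from_bit(bit_score, qlen[read_index], n_db_res)]
  hits <- hits[evalue <= e_max]
  if (nrow(hits) == 0L) return(empty_hits())

  ## best hit per group: bit score, then E-value, then database order
  data.table::setorder(hits, read_index, -bit_score, evalue, db_index)
  if (mode == "family_best") {
    hits[, family_id := db$family_id[db_index]]
    hits <- hits[!is.na(family_id)]
    if (nrow(hits) == 0L) return(empty_hits())
    hits <- hits[, .SD[1L], by = .(read_index, family_id)]
  } else {
    hits <- hits[, .SD[1L], by = read_index]
    hits[, family_id := db$family_id[db_index]]
  }

  ## map alignment intervals back to read bp coordinates (0-based half-open)
  w <- Biostrings::width(d$reads)[hits$read_index]
  fr <- hits$frame
  off_bp <- abs(fr) - 1L
  a <- off_bp + 3L * hits$q_aa_start
  b <- off_bp + 3L * hits$q_aa_end
  qstart <- ifelse(fr > 0L, a, w - b)
  qend <- ifelse(fr > 0L, b, w - a)

  alen <- hits$nmatch + hits$nmismatch + hits$gap_residues
  data.table::data.table(
    read_id = names(d$reads)[hits$read_index],
    accession = db$accession[hits$db_index],
    family_id = hits$family_id,
    frame = hits$frame,
    raw_score = hits$raw_score,
    bit_score = hits$bit_score,
    evalue = hits$evalue,
    identity = hits$nmatch / alen,
    alignment_length = alen,
    alignment_bp = 3L * alen,
    nmismatch = hits$nmismatch,
    gap_openings = hits$gap_openings,
    qstart = as.integer(qstart), qend = as.integer(qend),
    sstart = hits$sstart, send = hits$send,
    db_index = hits$db_index
  )
}

empty_hits <- function() {
  data.table::data.table(
    read_id = character(), accession = character(), family_id = character(),
    frame = integer(), raw_score = numeric(), bit_score = numeric(),
    evalue = numeric(), identity = numeric(), alignment_length = integer(),
    alignment_bp = integer(), nmismatch = integer(), gap_openings = integer(),
    qstart = integer(), qend = integer(), sstart = integer(), send = integer(),
    db_index = integer()
  )
}

#' Search one read against a reference panel
#'
#' Six-frame translated local alignment of a single read against a protein
#' panel grouped by gene family: for each family, the best hit over all six
#' frames and all family members by bit score; hits with E-value above
#' `e_max` are omitted. E-values use `m` = longest frame translation of the
#' read (residues) and `n` = total panel residues.
#'
#' @param read a single named DNA sequence (character vector of length 1
#'   with a name, or an [mg_dataset()] with one read).
#' @param panel ProteinRef data.frame with a `family_id` column.
#' @param scheme a [scoring_scheme()].
#' @param e_max maximum E-value (default 0.10).
#' @param use_seeds use the k-mer seed filter (default TRUE); set FALSE for
#'   exhaustive Smith-Waterman against every panel entry.
#' @return data.table of hits (one row per family at most), columns as in
#'   [recruit()].
#' @export
search_read <- function(read, panel, scheme = scoring_scheme(), e_max = 0.10,
                        use_seeds = TRUE) {
  d <- if (is(read, "mg_dataset")) read else {
    nm <- names(read) %||% "read1"
    mg_dataset(nm, as.character(read))
  }
  search_dataset(d, build_seed_index(panel), scheme = scheme, e_max = e_max,
                 mode = "family_best", use_seeds = use_seeds)
}

#' Write hits in tabular BLAST outfmt-6 layout
#'
#' Columns: query, subject, %identity, alignment length (residues),
#' mismatches, gap openings, qstart, qend, sstart, send, evalue, bitscore.
#' Printed coordinates are 1-based inclusive; query coordinates are in bp
#' on the read with qstart > qend for minus-frame hits, subject coordinates
#' in residues.
#'
#' @param hits hit table from [search_read()], [recruit()] or [confirm()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outfmt6 <- function(hits, path) {
  fwd <- hits$frame > 0L
  out <- data.frame(
    query = hits$read_id,
    subject = hits$accession,
    pident = sprintf("%.2f", 100 * hits$identity),
    length = hits$alignment_length,
    mismatch = hits$nmismatch,
    gapopen = hits$gap_openings,
    qstart = ifelse(fwd, hits$qstart + 1L, hits$qend),
    qend = ifelse(fwd, hits$qend, hits$qstart + 1L),
    sstart = hits$sstart + 1L,
    send = hits$send,
    evalue = sprintf("%.2g", hits$evalue),
    bitscore = sprintf("%.1f", hits$bit_score)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
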