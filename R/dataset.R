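#' Construct a metagenomic read dataset
#'
#' A light container for one sample's shotgun reads: a named
#' [Biostrings::DNAStringSet] plus a sample label. Read ids must be unique
#' and non-empty; sequences are upper-cased and restricted to
#' `{A,C,G,T,N}`. Coordinates elsewhere in the package are 0-based
#' half-open; stored sequences are the `+` orientation.
#'
#' @param ids character vector of read ids.
#' @param seqs character vector or `DNAStringSet` of read sequences.
#' @param sample_id sample label.
#' @return an object of class `mg_dataset`.
#' @export
mg_dataset <- function(ids, seqs, sample_id = "sample") {
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stopf("ids and seqs differ in length")
  if (any(!nzchar(ids))) stopf("read ids must be non-empty")
  if (anyDuplicated(ids)) stopf("duplicate read ids: %s",
                                paste(head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stopf("read %s contains characters outside {A,C,G,T,N}",
                      ids[which(bad)[1]])
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- ids
  structure(list(sample_id = sample_id, reads = reads), class = "mg_dataset")
}

#' @export
print.mg_dataset <- function(x, ...) {
  s <- if (length(x$reads)) dataset_stats(x) else
    list(n_reads = 0L, mean_length = NA, total_Mbp = 0)
  cat(sprintf("<mg_dataset> sample '%s': %d reads, mean length %s bp, %s Mbp\n",
              x$sample_id, s$n_reads, s$mean_length, s$total_Mbp))
  invisible(x)
}

#' @export
length.mg_dataset <- function(x) length(x$reads)

## subset a dataset by index, preserving order
dataset_subset <- function(d, idx) {
  d$reads <- d$reads[idx]
  d
}

#' Read sequences from FASTA or FASTQ
#'
#' @param path input file.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (by file extension).
#' @param sample_id sample label (defaults to the file base name).
#' @return an [mg_dataset()].
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  seqs <- Biostrings::readDNAStringSet(path, format = format)
  if (length(seqs) == 0L) warning("empty sequence file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  mg_dataset(ids, as.character(seqs),
             sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a dataset to FASTA or FASTQ
#'
#' FASTQ output carries uniform placeholder qualities (`I`), as the
#' pipeline does not model base quality.
#'
#' @param d an [mg_dataset()].
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(d, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(is(d, "mg_dataset"))
  if (format == "fasta") {
    Biostrings::writeXStringSet(d$reads, path, format = "fasta", width = 80L)
  } else {
    q <- Biostrings::BStringSet(strrep("I", Biostrings::width(d$reads)))
    Biostrings::writeXStringSet(d$reads, path, format = "fastq", qualities = q)
  }
  invisible(path)
}

#' Dataset summary statistics
#'
#' Reports the quantities used by the normalizations downstream: read
#' count, mean read length (rounded to integer bp), total bases, and total
#' megabases (rounded to integer Mbp, half away from zero).
#'
#' @param d an [mg_dataset()].
#' @return list with `n_reads`, `mean_length`, `total_bp`, `total_Mbp`.
#' @export
dataset_stats <- function(d) {
  stopifnot(is(d, "mg_dataset"))
  if (length(d$reads) == 0L) stopf("empty dataset: no statistics")
  w <- Biostrings::width(d$reads)
  total <- sum(as.numeric(w))
  list(
    n_reads = length(w),
    mean_length = as.integer(round_half_up(total / length(w), 0)),
    total_bp = total,
    total_Mbp = round_half_up(total / 1e6, 0)
  )
}

#' Draw a fixed-size random subsample of reads
#'
#' Uniform sampling without replacement; the selected reads keep their
#' input order. Deterministic for a fixed seed.
#'
#' @param d an [mg_dataset()].
#' @param n number of reads to keep; must satisfy `0 < n <= n_reads`.
#' @param seed integer seed.
#' @return an [mg_dataset()] with `n` reads.
#' @export
subsample <- function(d, n, seed = 1L) {
  stopifnot(is(d, "mg_dataset"))
  N <- length(d$reads)
  if (n <= 0) stopf("subsample size must be positive")
  if (n > N) stopf("subsample size %d exceeds dataset size %d", n, N)
  idx <- withr::with_seed(seed, sort(sample.int(N, n)))
  dataset_subset(d, idx)
}
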