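## identity of the shorter read over an end-free alignment against the
## longer read. Fast paths: exact prefix containment (454 replicates share
## the 5' start), then an ungapped column comparison; the gapped alignment
## is only computed for borderline pairs.
replicate_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  la <- nchar(a)
  if (substr(b, 1L, la) == a) return(1)
  ham <- sum(utf8ToInt(a) == utf8ToInt(substr(b, 1L, la))) / la
  if (ham >= 0.98 || ham < 0.5) return(ham)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1
  )
  max(ham, Biostrings::nmatch(pa) / la)
}

#' Remove 454-style artificial replicate reads
#'
#' Artificial replicates are a pyrosequencing artifact: multiple reads of
#' the same template that share the exact start position, possibly with 3'
#' truncation and a few base differences. Two reads are clustered as
#' replicates when their first `prefix_len` bases are identical and their
#' global identity over the shorter read's length is at least
#' `identity_threshold`. Clusters are single-linkage; the longest read of
#' each cluster is kept (ties broken by input order, or by read id when
#' `tie_break = "read_id"`, which makes the result invariant to input
#' order).
#'
#' @param d an [mg_dataset()].
#' @param prefix_len number of identical leading bases required (default 3).
#' @param identity_threshold minimum identity over the shorter read
#'   (default 0.90).
#' @param tie_break `"input_order"` (default) or `"read_id"`.
#' @return list with `dataset` (the dereplicated [mg_dataset()]) and
#'   `report`, a data.frame with one row per input read
#'   (`read_id`, `cluster_id`, `cluster_size`, `action` = keep/remove).
#' @export
remove_artificial_replicates <- function(d, prefix_len = 3L,
                                         identity_threshold = 0.90,
                                         tie_break = c("input_order", "read_id")) {
  stopifnot(is(d, "mg_dataset"))
  tie_break <- match.arg(tie_break)
  if (prefix_len < 1L) stopf("prefix_len must be >= 1")
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stopf("identity_threshold must be in (0, 1]")
  }
  n <- length(d$reads)
  ids <- names(d$reads)
  seqs <- as.character(d$reads)
  lens <- nchar(seqs)

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }

  prefix <- substr(seqs, 1L, prefix_len)
  for (grp in split(seq_len(n), prefix)) {
    m <- length(grp)
    if (m < 2L) next
    for (ii in seq_len(m - 1L)) {
      for (jj in seq(ii + 1L, m)) {
        i <- grp[ii]; j <- grp[jj]
        if (find(i) == find(j)) next
        if (replicate_identity(seqs[i], seqs[j]) >= identity_threshold) {
          union_(i, j)
        }
      }
    }
  }

  root <- vapply(seq_len(n), find, 1L)
  cluster_id <- match(root, unique(root))
  keep <- logical(n)
  for (members in split(seq_len(n), cluster_id)) {
    best <- members[lens[members] == max(lens[members])]
    if (length(best) > 1L && tie_break == "read_id") {
      best <- best[order(ids[best])]
    }
    keep[best[1L]] <- TRUE
  }

  report <- data.frame(
    read_id = ids,
    cluster_id = cluster_id,
    cluster_size = as.integer(table(cluster_id)[as.character(cluster_id)]),
    action = ifelse(keep, "keep", "remove"),
    stringsAsFactors = FALSE
  )
  list(dataset = dataset_subset(d, which(keep)), report = report)
}

#' Write a dereplication report as TSV
#'
#' @param report the `report` element of [remove_artificial_replicates()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_derep_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
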