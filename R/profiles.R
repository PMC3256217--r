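## genome-equivalent convention: 100 genomes of 3 Mbp = 300 Mbp,
## equivalent to 750,000 reads of 400 bp
READS_PER_100_GENOMES <- 750000

#' Normalize a hit count per 100 genome equivalents
#'
#' Scales a raw hit count to the count expected in 100 genome equivalents
#' (100 x 3 Mbp = 300 Mbp, equivalent to 750,000 reads of 400 bp), i.e.
#' `raw_count * 750000 / n_reads`, rounded half away from zero to one
#' decimal. The divisor is the dataset's read count, not its base count:
#' only that convention yields the single-hit increments (e.g.
#' 750000/108203 = 6.9) that make values comparable across datasets of
#' different sizes.
#'
#' @param raw_count non-negative hit count(s).
#' @param n_reads dataset size(s) in reads (post-dereplication).
#' @return normalized value(s), one decimal.
#' @examples
#' normalize_per_100_genomes(9, 108203)  # 62.4
#' @export
normalize_per_100_genomes <- function(raw_count, n_reads) {
  if (any(n_reads <= 0)) stopf("n_reads must be positive")
  if (any(raw_count < 0)) stopf("raw_count must be non-negative")
  round_half_up(raw_count * READS_PER_100_GENOMES / n_reads, 1)
}

#' Add per-100-genomes values to a count table
#'
#' @param counts count table from [aggregate_counts()] (`family_id`,
#'   `group`, `sample_id`, `raw_count`).
#' @param sample_n_reads named vector: sample id -> dataset size in reads
#'   backing that sample's counts.
#' @return the table with `n_reads` and `per100` columns added.
#' @export
normalize_abundance <- function(counts, sample_n_reads) {
  counts <- data.table::as.data.table(counts)
  missing <- setdiff(unique(counts$sample_id), names(sample_n_reads))
  if (length(missing)) stopf("no dataset size for sample '%s'", missing[1])
  counts[, n_reads := sample_n_reads[sample_id]]
  counts[, per100 := normalize_per_100_genomes(raw_count, n_reads)]
  counts[]
}

#' Per-family totals of a normalized abundance table
#'
#' Totals are sums of the *rounded* per-group values (not a re-normalized
#' raw-count sum), which is how printed table totals relate to their
#' components.
#'
#' @param tab table from [normalize_abundance()].
#' @return data.table `family_id`, `sample_id`, `raw_count`, `total_per100`.
#' @export
table_totals <- function(tab) {
  tab <- data.table::as.data.table(tab)
  if (nrow(tab) == 0L) stopf("empty abundance table")
  out <- tab[, .(raw_count = sum(raw_count),
                 total_per100 = round_half_up(sum(per100), 1)),
             by = .(family_id, sample_id)]
  data.table::setorder(out, family_id, sample_id)
  out[]
}

#' Subsampling normalization: re-run the mining on a fixed-size subsample
#'
#' The alternative normalization: draw `n` reads uniformly without
#' replacement from the dataset, re-run recruitment and confirmation on the
#' subsample, and report raw per-family confirmed counts. When `n` exceeds
#' the dataset size the full dataset is used with a warning.
#'
#' @param d a dereplicated [mg_dataset()].
#' @param panel recruitment panel (ProteinRef data.frame).
#' @param confirmation_db confirmation database (ProteinRef data.frame).
#' @param scheme a [scoring_scheme()].
#' @param n subsample size (default 100000 reads).
#' @param seed integer seed for the subsample.
#' @param e_max recruitment threshold (default 0.10).
#' @param synonym_map see [confirm()].
#' @return data.table `family_id`, `sample_id`, `raw_count` on the
#'   subsample.
#' @export
normalize_by_subsampling <- function(d, panel, confirmation_db,
                                     scheme = scoring_scheme(), n = 100000,
                                     seed = 1L, e_max = 0.10,
                                     synonym_map = default_synonym_map()) {
  stopifnot(is(d, "mg_dataset"))
  if (n > length(d$reads)) {
    warning(sprintf("subsample size %d exceeds dataset size %d; using all reads",
                    n, length(d$reads)))
    sub <- d
  } else {
    sub <- subsample(d, n, seed)
  }
  rec <- recruit(sub, panel, scheme = scheme, e_max = e_max)
  conf <- confirm(rec, sub, confirmation_db, scheme = scheme,
                  synonym_map = synonym_map)
  counts <- aggregate_counts(conf)
  if (nrow(counts) == 0L) {
    return(data.table::data.table(family_id = character(),
                                  sample_id = character(),
                                  raw_count = integer()))
  }
  counts[, .(raw_count = sum(raw_count)), by = .(family_id, sample_id)]
}

## ranks with average ties, no package call
avg_rank <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  r[o] <- seq_along(x)
  for (v in unique(x[duplicated(x)])) {
    i <- which(x == v)
    r[i] <- mean(r[i])
  }
  r
}

## Spearman rank correlation with average ranks, implemented directly
spearman_rho <- function(x, y) {
  rx <- avg_rank(x); ry <- avg_rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

#' Rank concordance between two normalizations
#'
#' Spearman rank correlation (average ranks for ties) between the
#' per-100-genomes family totals and the subsample family counts over
#' matching (family, sample) cells. The two procedures measure the same
#' underlying per-read hit densities, so high concordance validates that
#' the per-100-genomes rescaling does not distort cross-sample comparisons.
#' P-values use the large-sample t approximation by default; an exact
#' permutation test is available for fewer than 10 pairs.
#'
#' @param per100_tab output of [table_totals()] (uses `total_per100`).
#' @param subsample_tab output of [normalize_by_subsampling()].
#' @param method `"t"` (default) or `"exact"` (all permutations; n <= 8).
#' @return list with `rho`, `p_value`, `n` (paired cells).
#' @export
concordance <- function(per100_tab, subsample_tab, method = c("t", "exact")) {
  method <- match.arg(method)
  a <- data.table::as.data.table(per100_tab)
  b <- data.table::as.data.table(subsample_tab)
  m <- merge(a[, .(family_id, sample_id, x = total_per100)],
             b[, .(family_id, sample_id, y = raw_count)],
             by = c("family_id", "sample_id"), all = TRUE)
  m[is.na(m)] <- 0
  n <- nrow(m)
  if (n < 5L) stopf("concordance needs at least 5 paired cells (got %d)", n)
  rho <- spearman_rho(m$x, m$y)
  if (method == "t") {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  } else {
    if (n > 8L) stopf("exact permutation test limited to 8 pairs (got %d)", n)
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(p_) spearman_rho(m$x, m$y[p_]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p_value = p, n = n)
}

## all permutations of 1..n as a matrix (n small)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- nrow(sub)
    out[r + seq_len(rows), ] <- cbind(rep(i, rows),
                                      matrix(setdiff(1:n, i)[sub], rows))
    r <- r + rows
  }
  out
}

#' Genome-size-corrected taxonomic profile
#'
#' Assigns each read to the organism of its best database hit (E-value at
#' most `e_max` and alignment span on the read at least `min_aln_bp`), then
#' corrects fragment counts for genome size: for equal true abundance, an
#' organism with a larger genome yields proportionally more fragments, so
#' corrected abundance divides the fragment count by the genome size.
#' Relative fractions are re-normalized over the classified organisms.
#'
#' @param d an [mg_dataset()].
#' @param genome_db ProteinRef-style data.frame with additional columns
#'   `organism` and `genome_size` (bp); entries without a genome size are
#'   excluded with a warning.
#' @param scheme a [scoring_scheme()].
#' @param e_max annotation threshold (default 1e-5).
#' @param min_aln_bp minimum alignment span on the read (default 50 bp).
#' @param use_seeds use the k-mer seed filter (default TRUE).
#' @return data.frame `organism`, `fragment_count`, `genome_size`,
#'   `corrected_abundance`, `fraction`.
#' @export
taxon_profile <- function(d, genome_db, scheme = scoring_scheme(),
                          e_max = 1e-5, min_aln_bp = 50, use_seeds = TRUE) {
  stopifnot(is(d, "mg_dataset"))
  if (is.null(genome_db$organism)) stopf("genome_db needs an 'organism' column")
  no_size <- is.na(genome_db$genome_size)
  if (any(no_size)) {
    warning(sprintf("%d genome(s) without size excluded: %s", sum(no_size),
                    paste(unique(genome_db$organism[no_size]), collapse = ", ")))
    genome_db <- genome_db[!no_size, ]
  }
  if (nrow(genome_db) == 0L) stopf("no genomes with sizes in genome_db")
  hits <- search_dataset(d, build_seed_index(genome_db), scheme = scheme,
                         e_max = e_max, mode = "db_best",
                         use_seeds = use_seeds)
  hits <- hits[hits$alignment_bp >= min_aln_bp, ]
  org <- genome_db$organism[hits$db_index]
  counts <- table(factor(org, levels = unique(genome_db$organism)))
  size <- genome_db$genome_size[match(names(counts), genome_db$organism)]
  corrected <- as.numeric(counts) / size
  data.frame(
    organism = names(counts),
    fragment_count = as.integer(counts),
    genome_size = size,
    corrected_abundance = corrected,
    fraction = if (sum(corrected) > 0) corrected / sum(corrected) else corrected,
    row.names = NULL
  )
}

#' Lay out an abundance table like a published per-family table
#'
#' Rows are taxon groups plus a Total row; columns the time-course samples.
#'
#' @param tab output of [normalize_abundance()].
#' @param family family id to lay out.
#' @param samples column order (default uncont, t0, t1m, t1y).
#' @param value `"per100"` (default) or `"raw_count"`.
#' @return data.frame in display layout.
#' @export
layout_family_table <- function(tab, family,
                                samples = c("uncont", "t0", "t1m", "t1y"),
                                value = c("per100", "raw_count")) {
  value <- match.arg(value)
  tab <- data.table::as.data.table(tab)[family_id == family]
  samples <- intersect(samples, unique(c(samples, tab$sample_id)))
  groups <- sort(unique(tab$group))
  out <- data.frame(group = c(groups, "Total"))
  for (s in samples) {
    v <- vapply(groups, function(g) {
      x <- tab[group == g & sample_id == s][[value]]
      if (length(x)) sum(x) else 0
    }, 0)
    out[[s]] <- c(v, round_half_up(sum(v), 1))
  }
  out
}
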