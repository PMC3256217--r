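#' Specify a synthetic 454-style metagenome
#'
#' Describes one pooled pyrosequencing dataset: background reads of i.i.d.
#' uniform nucleotides (so they essentially never pass the recruitment
#' threshold against a desk-scale panel), planted gene fragments
#' reverse-translated from database proteins, and artificial replicate
#' reads appended as exact copies with optional 3' truncation (the 454
#' same-start artifact targeted by dereplication).
#'
#' @param sample_id sample label.
#' @param n_reads total emitted reads (including artificial replicates).
#' @param read_length_mean,read_length_sd read length distribution in bp.
#' @param duplicate_rate fraction of emitted reads that are artificial
#'   replicates, in `[0, 1)`.
#' @param taxon_abundances named fractions (summing to 1) used to label the
#'   origin lineage of background reads in the truth table.
#' @param planted_gene_load data.frame `family_id`, `group`, `expected`:
#'   expected (Poisson) planted read counts per family and taxon group.
#' @param mutation_rate per-base substitution probability on planted
#'   fragments.
#' @param seed integer seed.
#' @return an object of class `metagenome_spec`.
#' @export
metagenome_spec <- function(sample_id, n_reads,
                            read_length_mean = 400, read_length_sd = 50,
                            duplicate_rate = 0,
                            taxon_abundances = c("uncultured/unclassified" = 1),
                            planted_gene_load = NULL,
                            mutation_rate = 0.02, seed = 1L) {
  if (n_reads <= 0) stopf("n_reads must be positive")
  if (duplicate_rate < 0 || duplicate_rate >= 1) {
    stopf("duplicate_rate must be in [0, 1)")
  }
  if (abs(sum(taxon_abundances) - 1) > 1e-9) {
    stopf("taxon_abundances must sum to 1 (got %g)", sum(taxon_abundances))
  }
  if (mutation_rate < 0 || mutation_rate >= 1) {
    stopf("mutation_rate must be in [0, 1)")
  }
  if (is.null(planted_gene_load)) {
    planted_gene_load <- data.frame(family_id = character(),
                                    group = character(),
                                    expected = numeric())
  }
  structure(
    list(sample_id = sample_id, n_reads = as.integer(n_reads),
         read_length_mean = read_length_mean, read_length_sd = read_length_sd,
         duplicate_rate = duplicate_rate, taxon_abundances = taxon_abundances,
         planted_gene_load = planted_gene_load,
         mutation_rate = mutation_rate, seed = as.integer(seed)),
    class = "metagenome_spec"
  )
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chr <- function(s) {
  paste(rev(REVCOMP[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

## substitute bases at rate p (always to a different base)
mutate_dna <- function(s, p) {
  if (p <= 0) return(s)
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(b)) < p & b != "N")
  if (length(hit)) {
    b[hit] <- vapply(b[hit],
                     function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
                     "")
  }
  paste(b, collapse = "")
}

## n random reads of given lengths, i.i.d. uniform nucleotides
random_reads <- function(lens) {
  if (length(lens) == 0L) return(character())
  chars <- sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE)
  grp <- rep.int(seq_along(lens), lens)
  unname(vapply(split(chars, grp), paste, "", collapse = ""))
}

read_lengths <- function(n, mean, sd, min_len) {
  pmax(min_len, as.integer(round(rnorm(n, mean, sd))))
}

#' Generate a synthetic metagenome with a per-read truth table
#'
#' Emits exactly `spec$n_reads` reads: background reads, planted gene
#' fragments (reverse-translated with uniform codon choice from database
#' proteins matching each load's family and taxon group, placed on a
#' random strand, substituted at `mutation_rate`), and artificial replicate
#' copies appended until `duplicate_rate` of the emitted reads are
#' replicates. Planted counts are Poisson draws around each load's
#' expectation. Planted fragments are at least 150 bp so they remain
#' recoverable by translated search.
#'
#' @param spec a [metagenome_spec()].
#' @param panel ProteinRef data.frame supplying planting sources; must
#'   contain a protein for every (family, group) in the planted load.
#' @return list with `dataset` (an [mg_dataset()]) and `truth`, a
#'   data.frame with one row per emitted read: `read_id`, `origin_group`,
#'   `planted_family`, `source_accession`, `is_artificial_replicate`,
#'   `source_read_id`.
#' @export
generate_metagenome <- function(spec, panel) {
  stopifnot(is(spec, "metagenome_spec"))
  load <- spec$planted_gene_load
  if (nrow(load) > 0 && nrow(panel) == 0L) stopf("empty panel with planted load")

  withr::with_seed(spec$seed, {
    n_total <- spec$n_reads
    n_dup <- as.integer(round(spec$duplicate_rate * n_total))
    n_base <- n_total - n_dup

    ## planted read counts per load row (Poisson)
    counts <- if (nrow(load)) rpois(nrow(load), load$expected) else integer()
    n_planted <- sum(counts)
    if (n_planted > n_base) {
      stopf("planted gene load (%d reads) exceeds available reads (%d)",
            n_planted, n_base)
    }

    panel_group <- lineage_group(panel$phylum, panel$class)

    p_seq <- character(n_planted); p_fam <- character(n_planted)
    p_grp <- character(n_planted); p_acc <- character(n_planted)
    k <- 0L
    for (i in seq_len(nrow(load))) {
      if (counts[i] == 0L) next
      cand <- which(panel$family_id == load$family_id[i] &
                      panel_group == load$group[i])
      if (length(cand) == 0L) {
        stopf("no panel protein for family '%s' in group '%s'",
              load$family_id[i], load$group[i])
      }
      for (j in seq_len(counts[i])) {
        k <- k + 1L
        src <- cand[sample.int(length(cand), 1L)]
        cds <- reverse_translate(panel$sequence[src])
        rl <- min(nchar(cds),
                  read_lengths(1L, spec$read_length_mean,
                               spec$read_length_sd, 150L))
        start <- sample.int(nchar(cds) - rl + 1L, 1L)
        frag <- mutate_dna(substr(cds, start, start + rl - 1L),
                           spec$mutation_rate)
        if (runif(1) < 0.5) frag <- revcomp_chr(frag)
        p_seq[k] <- frag
        p_fam[k] <- load$family_id[i]
        p_grp[k] <- load$group[i]
        p_acc[k] <- panel$accession[src]
      }
    }

    ## background reads
    n_bg <- n_base - n_planted
    bg_seq <- random_reads(read_lengths(n_bg, spec$read_length_mean,
                                        spec$read_length_sd, 50L))
    bg_grp <- if (n_bg > 0L) {
      sample(names(spec$taxon_abundances), n_bg, replace = TRUE,
             prob = spec$taxon_abundances)
    } else character()

    ## interleave planted and background reads
    ord <- sample.int(n_base)
    seqs <- c(p_seq, bg_seq)[ord]
    grp <- c(p_grp, bg_grp)[ord]
    fam <- c(p_fam, rep(NA_character_, n_bg))[ord]
    acc <- c(p_acc, rep(NA_character_, n_bg))[ord]

    ## artificial replicates: exact copies, optional 3' truncation
    src_idx <- if (n_dup > 0L) sample.int(n_base, n_dup, replace = TRUE) else integer()
    dup_seq <- character(n_dup)
    for (j in seq_len(n_dup)) {
      s <- seqs[src_idx[j]]
      if (runif(1) < 0.5) {
        keep <- max(50L, as.integer(ceiling(nchar(s) * runif(1, 0.8, 1))))
        s <- substr(s, 1L, keep)
      }
      dup_seq[j] <- s
    }

    ids <- sprintf("%s_r%06d", spec$sample_id, seq_len(n_total))
    truth <- data.frame(
      read_id = ids,
      origin_group = c(grp, grp[src_idx]),
      planted_family = c(fam, fam[src_idx]),
      source_accession = c(acc, acc[src_idx]),
      is_artificial_replicate = c(rep(FALSE, n_base), rep(TRUE, n_dup)),
      source_read_id = c(rep(NA_character_, n_base), ids[src_idx]),
      stringsAsFactors = FALSE
    )
    list(dataset = mg_dataset(ids, c(seqs, dup_seq), spec$sample_id),
         truth = truth)
  })
}

## default post-dereplication read counts of the emulated time course
TIMECOURSE_READS <- c(uncont = 457781, t0 = 364725, t1m = 108203, t1y = 287705)
TIMECOURSE_LENGTHS <- c(uncont = 441, t0 = 343, t1m = 327, t1y = 350)

timecourse_backgrounds <- function() {
  list(
    uncont = c("uncultured/unclassified" = 0.40, "Acidobacteria" = 0.20,
               "Actinobacteria" = 0.10, "Alphaproteobacteria" = 0.10,
               "Betaproteobacteria" = 0.10, "Gammaproteobacteria" = 0.10),
    t0  = c("Gammaproteobacteria" = 0.35, "Actinobacteria" = 0.20,
            "Alphaproteobacteria" = 0.15, "uncultured/unclassified" = 0.30),
    t1m = c("Gammaproteobacteria" = 0.35, "Actinobacteria" = 0.20,
            "Alphaproteobacteria" = 0.15, "uncultured/unclassified" = 0.30),
    t1y = c("Actinobacteria" = 0.30, "Alphaproteobacteria" = 0.25,
            "Gammaproteobacteria" = 0.10, "uncultured/unclassified" = 0.35)
  )
}

#' Generate the four-sample synthetic biopile time course
#'
#' Emulates a pooled 454 sequencing time course of a hydrocarbon
#' bioremediation biopile: an uncontaminated control, the freshly
#' contaminated/excavated soil (t0), one month (t1m) and one year (t1y)
#' into treatment. Read counts default to 457,781 / 364,725 / 108,203 /
#' 287,705 multiplied by `scale` (default 0.01, desk scale). Planted gene
#' loads follow the package's default design: Gammaproteobacteria-dominated
#' alkB at t0/t1m, Actinobacteria/Alphaproteobacteria-dominated at t1y,
#' about a tenth of the load in the uncontaminated control. Loads are
#' absolute expected read counts and are *not* multiplied by `scale`, so
#' subsampling `100000 * scale` reads reproduces the full-scale counting
#' regime.
#'
#' @param db ProteinRef data.frame used as planting source (normally the
#'   confirmation database of [generate_reference_panel()], which carries a
#'   member per taxon group).
#' @param seed integer master seed; per-sample seeds are derived from it.
#' @param scale positive factor applied to the default read counts.
#' @param duplicate_rate artificial-replicate fraction per sample.
#' @param mutation_rate per-base substitution rate on planted fragments.
#' @param loads load table (`family_id`, `group`, one column per sample);
#'   defaults to the package design described above.
#' @return named list (`uncont`, `t0`, `t1m`, `t1y`) of
#'   `list(dataset, truth, spec)`.
#' @export
generate_timecourse <- function(db, seed = 1L, scale = 0.01,
                                duplicate_rate = 0.1, mutation_rate = 0.02,
                                loads = timecourse_loads()) {
  if (scale <= 0) stopf("scale factor must be positive")
  bgs <- timecourse_backgrounds()
  out <- list()
  for (i in seq_along(TIMECOURSE_READS)) {
    sname <- names(TIMECOURSE_READS)[i]
    spec <- metagenome_spec(
      sample_id = sname,
      n_reads = as.integer(round(TIMECOURSE_READS[[sname]] * scale)),
      read_length_mean = TIMECOURSE_LENGTHS[[sname]],
      read_length_sd = 50,
      duplicate_rate = duplicate_rate,
      taxon_abundances = bgs[[sname]],
      planted_gene_load = data.frame(family_id = loads$family_id,
                                     group = loads$group,
                                     expected = loads[[sname]]),
      mutation_rate = mutation_rate,
      seed = child_seed(seed, i)
    )
    out[[sname]] <- c(generate_metagenome(spec, db), list(spec = spec))
  }
  out
}

#' Write a truth table as TSV
#'
#' @param truth truth data.frame from [generate_metagenome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
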