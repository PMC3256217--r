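#' Recruit reads by gene-family reference search
#'
#' Stage one of the mining procedure: every read is compared, in six-frame
#' translation, against the family reference panel, and every (read,
#' family) pair whose best alignment reaches E-value `e_max` or better is
#' recruited. The threshold is deliberately permissive (default E < 0.10)
#' so that fragments from distantly related organisms are not missed;
#' specificity is restored at the confirmation stage. A read may be
#' recruited by several families; the conflict is resolved by [confirm()].
#'
#' @param d a dereplicated [mg_dataset()].
#' @param panel ProteinRef data.frame with `family_id` set.
#' @param scheme a [scoring_scheme()].
#' @param e_max recruitment E-value threshold (default 0.10).
#' @param use_seeds use the k-mer seed filter (default TRUE).
#' @return data.table of recruitment records: `sample_id`, `read_id`,
#'   `family_id`, recruit alignment columns (`accession`, `evalue`,
#'   `bit_score`, `identity`, `alignment_length`, `frame`, ...), and
#'   `status = "recruited"`.
#' @export
recruit <- function(d, panel, scheme = scoring_scheme(), e_max = 0.10,
                    use_seeds = TRUE) {
  stopifnot(is(d, "mg_dataset"))
  if (anyDuplicated(names(d$reads))) {
    stopf("duplicate read ids: dataset must be dereplicated first")
  }
  hits <- search_dataset(d, build_seed_index(panel), scheme = scheme,
                         e_max = e_max, mode = "family_best",
                         use_seeds = use_seeds)
  hits[, `:=`(sample_id = d$sample_id, status = "recruited")]
  data.table::setcolorder(hits, c("sample_id", "read_id", "family_id"))
  hits[]
}

#' Confirm recruited reads by best hit against a broad protein database
#'
#' Stage two: each recruited read is searched against the confirmation
#' database (target families, closely related synonym families, and
#' unrelated proteins) and its single best hit — highest bit score, ties
#' broken by lower E-value then database order — decides its fate. A record
#' is *confirmed* when the best hit's family is the recruiting family or an
#' allowed synonym (catechol 2,3-dioxygenase accepts biphenyl-2,3-diol
#' 1,2-dioxygenase and 1,2-dihydroxynaphthalene dioxygenase); otherwise it
#' is *discarded*. The taxon group (phylum; class for Proteobacteria) and
#' genus are copied from the best hit's lineage. A read recruited by
#' several families keeps only the family supported by its best
#' confirmation hit.
#'
#' @param records recruitment records from [recruit()].
#' @param d the [mg_dataset()] the records came from (supplies sequences).
#' @param confirmation_db ProteinRef data.frame (families + decoys).
#' @param scheme a [scoring_scheme()].
#' @param synonym_map named list family -> accepted families
#'   (default [default_synonym_map()]).
#' @param use_seeds use the k-mer seed filter (default TRUE).
#' @return the records with `status` set to `"confirmed"` or
#'   `"discarded"`, plus `confirm_accession`, `confirm_family`,
#'   `confirm_evalue`, `confirm_bit`, `assigned_group`, `assigned_genus`
#'   and `reason` (for discarded records).
#' @export
confirm <- function(records, d, confirmation_db, scheme = scoring_scheme(),
                    synonym_map = default_synonym_map(), use_seeds = TRUE) {
  if (nrow(confirmation_db) == 0L) stopf("empty confirmation database")
  records <- data.table::as.data.table(records)
  out <- data.table::copy(records)
  out[, `:=`(status = "discarded", reason = "no confirmation hit",
             confirm_accession = NA_character_, confirm_family = NA_character_,
             confirm_evalue = NA_real_, confirm_bit = NA_real_,
             assigned_group = NA_character_, assigned_genus = NA_character_)]
  if (nrow(out) == 0L) return(out[])

  ids <- unique(out$read_id)
  sub <- dataset_subset(d, match(ids, names(d$reads)))
  best <- search_dataset(sub, build_seed_index(confirmation_db),
                         scheme = scheme, e_max = Inf, mode = "db_best",
                         use_seeds = use_seeds)
  bi <- match(out$read_id, best$read_id)
  hit <- !is.na(bi)
  dbrow <- best$db_index[bi[hit]]
  out$confirm_accession[hit] <- best$accession[bi[hit]]
  out$confirm_family[hit] <- confirmation_db$family_id[dbrow]
  out$confirm_evalue[hit] <- best$evalue[bi[hit]]
  out$confirm_bit[hit] <- best$bit_score[bi[hit]]
  out$assigned_group[hit] <- lineage_group(confirmation_db$phylum[dbrow],
                                           confirmation_db$class[dbrow])
  out$assigned_genus[hit] <- confirmation_db$genus[dbrow]

  accepted <- mapply(function(fam, cfam) {
    !is.na(cfam) && cfam %in% (synonym_map[[fam]] %||% fam)
  }, out$family_id, out$confirm_family)
  out$status[hit & accepted] <- "confirmed"
  out$reason[hit & accepted] <- NA_character_
  out$reason[hit & !accepted] <- "best hit outside recruiting family"

  ## a read confirmed under several recruiting families keeps the one with
  ## the best recruitment bit score
  conf <- which(out$status == "confirmed")
  if (length(conf) > 1L) {
    o <- conf[order(out$read_id[conf], -out$bit_score[conf])]
    dupes <- o[duplicated(out$read_id[o])]
    out$status[dupes] <- "discarded"
    out$reason[dupes] <- "read assigned to another family"
  }
  out[]
}

#' Diagnostic report on weakly recruited reads
#'
#' Tabulates the confirmation rate of recruits above and below an E-value
#' threshold (default 1e-30). Reads recruited with E-values above the
#' threshold generally fail confirmation — the diagnostic that shows the
#' permissive recruitment threshold captured everything related to the
#' target genes. No records are removed; confirmation is the filter.
#'
#' @param records confirmed/discarded records from [confirm()].
#' @param e_threshold E-value split point (default 1e-30).
#' @return data.frame with one row per stratum (`recruit E <= threshold`,
#'   `recruit E > threshold`): `n`, `n_confirmed`, `confirmation_rate`.
#' @export
flag_weak_recruits <- function(records, e_threshold = 1e-30) {
  if (nrow(records) == 0L) {
    return(data.frame(stratum = character(), n = integer(),
                      n_confirmed = integer(), confirmation_rate = numeric()))
  }
  weak <- records$evalue > e_threshold
  strat <- function(mask, label) {
    data.frame(stratum = label, n = sum(mask),
               n_confirmed = sum(records$status[mask] == "confirmed"),
               confirmation_rate =
                 if (sum(mask)) sum(records$status[mask] == "confirmed") / sum(mask)
                 else NA_real_)
  }
  rbind(strat(!weak, sprintf("recruit E <= %g", e_threshold)),
        strat(weak, sprintf("recruit E > %g", e_threshold)))
}

#' Aggregate confirmed records into an abundance count table
#'
#' Counts confirmed reads per gene family, taxon group and sample.
#' Taxonomic resolution is deliberately coarse — phylum, or class for
#' Proteobacteria — because many of these catabolic genes ride on mobile
#' elements and genus-level assignment of short fragments is unreliable.
#' `"uncultured/unclassified"`, `"Eukaryotes"` and `"synthetic construct"`
#' are legal groups; records with no resolvable lineage are routed to
#' `"uncultured/unclassified"` with a warning.
#'
#' @param records records from [confirm()]; only `status == "confirmed"`
#'   rows are counted.
#' @param level `"phylum_class"` (default) or `"genus"` (genus-level
#'   roll-up; unclassified genera grouped as `"unclassified"`).
#' @return data.table with `family_id`, `group` (and `genus` at genus
#'   level), `sample_id`, `raw_count`.
#' @export
aggregate_counts <- function(records, level = c("phylum_class", "genus")) {
  level <- match.arg(level)
  rec <- data.table::as.data.table(records)[status == "confirmed"]
  if (nrow(rec) == 0L) {
    return(data.table::data.table(family_id = character(), group = character(),
                                  sample_id = character(), raw_count = integer()))
  }
  if (anyNA(rec$assigned_group)) {
    warning("records with unknown lineage routed to uncultured/unclassified")
    rec[is.na(assigned_group), assigned_group := "uncultured/unclassified"]
  }
  if (level == "phylum_class") {
    out <- rec[, .(raw_count = .N),
               by = .(family_id, group = assigned_group, sample_id)]
  } else {
    rec[is.na(assigned_genus), assigned_genus := "unclassified"]
    out <- rec[, .(raw_count = .N),
               by = .(family_id, group = assigned_group,
                      genus = assigned_genus, sample_id)]
  }
  data.table::setorder(out, family_id, group, sample_id)
  out[]
}

#' Write confirmed records as TSV
#'
#' @param records records from [confirm()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  cols <- intersect(
    c("sample_id", "read_id", "family_id", "status", "reason",
      "assigned_group", "assigned_genus", "evalue", "bit_score", "identity",
      "accession", "confirm_accession", "confirm_family", "confirm_evalue"),
    names(records))
  utils::write.table(as.data.frame(records)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
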