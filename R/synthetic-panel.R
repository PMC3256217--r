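## reverse-translate a protein with uniform random synonymous codons
## (composition-neutral: avoids codon-bias artifacts in alignment tests)
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), gc)
    }
    tab
  }
})

reverse_translate <- function(protein) {
  tab <- codon_table()
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(tab[aa], function(cs) cs[sample.int(length(cs), 1L)], "")
  paste(codons, collapse = "")
}

## validated ProteinRef table
protein_ref_table <- function(accession, description, family_id, ec,
                              phylum, class, genus, sequence) {
  df <- data.frame(accession = accession, description = description,
                   family_id = family_id, ec = ec, phylum = phylum,
                   class = class, genus = genus, sequence = sequence,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$accession)) {
    stopf("duplicate protein accession: %s",
          df$accession[duplicated(df$accession)][1])
  }
  bad <- !is.na(df$class) & df$phylum != "Proteobacteria"
  if (any(bad)) stopf("lineage class is only valid under Proteobacteria (%s)",
                      df$accession[bad][1])
  df
}

#' Generate a synthetic reference panel and confirmation database
#'
#' Builds, deterministically for a given seed, the two protein databases
#' the two-stage mining procedure needs:
#'
#' * the *reference panel*: `n_reference_proteins` proteins per family
#'   (by default one Gram-positive and one Gram-negative lineage), used as
#'   recruitment queries;
#' * the *confirmation database*: a superset of the panel holding one
#'   family member per member taxon (so best-hit confirmation can assign
#'   diverse lineages), closely related synonym families for catechol
#'   2,3-dioxygenase (biphenyl-2,3-diol 1,2-dioxygenase and
#'   1,2-dihydroxynaphthalene dioxygenase), and at least 20% unrelated
#'   decoy proteins.
#'
#' Family members are derived from a common random ancestor so that
#' within-family global identity stays above 60%; decoys are independent
#' random proteins (global identity to any family member well below 25%).
#'
#' @param specs list of [family_spec()] (default [default_family_specs()]).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param include_synonyms generate the C23O synonym families (default TRUE
#'   when a `C23O` spec is present).
#' @param decoy_fraction decoys as a fraction of family entries
#'   (default 0.25, i.e. 20% of the database).
#' @return list with `panel` and `confirmation_db`, both ProteinRef
#'   data.frames (`accession`, `description`, `family_id`, `ec`, `phylum`,
#'   `class`, `genus`, `sequence`).
#' @export
generate_reference_panel <- function(specs = default_family_specs(),
                                     seed = 1L,
                                     include_synonyms = NULL,
                                     decoy_fraction = 0.25) {
  ids <- vapply(specs, function(s) s$family_id, "")
  if (anyDuplicated(ids)) {
    stopf("duplicate family_id in panel spec: %s", ids[duplicated(ids)][1])
  }
  include_synonyms <- include_synonyms %||% ("C23O" %in% ids)

  withr::with_seed(seed, {
    member_rows <- list()
    panel_rows <- list()
    ancestors <- list()

    make_family <- function(family_id, name, ec, len, groups, ancestor,
                            n_refs = 0L) {
      ## order so Gram+ then Gammaproteobacteria lineages head the panel
      pref <- c("Actinobacteria", "Firmicutes", "Gammaproteobacteria",
                "Alphaproteobacteria", "Betaproteobacteria")
      groups <- c(intersect(pref, groups), setdiff(groups, pref))
      lin <- group_lineage(groups)
      seqs <- vapply(seq_along(groups), function(i)
        mutate_protein(ancestor, 0.12), "")
      rows <- protein_ref_table(
        accession = sprintf("%s_%02d", toupper(family_id), seq_along(groups)),
        description = sprintf("%s [%s]", name, groups),
        family_id = family_id, ec = ec,
        phylum = lin$phylum, class = lin$class, genus = lin$genus,
        sequence = seqs
      )
      member_rows[[family_id]] <<- rows
      if (n_refs > 0L) {
        if (n_refs > nrow(rows)) {
          ## panel larger than the member-taxon list: add extra variants
          extra <- n_refs - nrow(rows)
          add <- rows[rep(1L, extra), ]
          add$accession <- sprintf("%s_R%02d", toupper(family_id), seq_len(extra))
          add$sequence <- vapply(seq_len(extra), function(i)
            mutate_protein(ancestor, 0.12), "")
          rows <- rbind(rows, add)
          member_rows[[family_id]] <<- rows
        }
        panel_rows[[family_id]] <<- rows[seq_len(n_refs), ]
      }
    }

    for (s in specs) {
      ancestors[[s$family_id]] <- random_protein(s$protein_length)
      make_family(s$family_id, s$name, s$ec, s$protein_length,
                  s$member_groups, ancestors[[s$family_id]],
                  n_refs = s$n_reference_proteins)
    }

    if (include_synonyms && "C23O" %in% ids) {
      loads <- timecourse_loads()
      for (i in seq_len(nrow(SYNONYM_INFO))) {
        sy <- SYNONYM_INFO[i, ]
        groups <- unique(loads$group[loads$family_id == sy$family_id])
        if (length(groups) == 0L) groups <- "Gammaproteobacteria"
        anc <- mutate_protein(ancestors[["C23O"]], 0.18)
        make_family(sy$family_id, sy$name, sy$ec, sy$protein_length,
                    groups, anc, n_refs = 0L)
      }
    }

    members <- do.call(rbind, member_rows)
    n_decoy <- ceiling(decoy_fraction * nrow(members))
    decoy_groups <- sample(GROUP_INFO$group, n_decoy, replace = TRUE)
    dlin <- group_lineage(decoy_groups)
    decoys <- protein_ref_table(
      accession = sprintf("DECOY_%03d", seq_len(n_decoy)),
      description = "hypothetical protein (synthetic decoy)",
      family_id = NA_character_, ec = NA_character_,
      phylum = dlin$phylum, class = dlin$class, genus = dlin$genus,
      sequence = vapply(sample(200:500, n_decoy, replace = TRUE),
                        random_protein, "")
    )

    panel <- do.call(rbind, panel_rows)
    rownames(panel) <- NULL
    confirmation_db <- rbind(members, decoys)
    rownames(confirmation_db) <- NULL
    list(panel = panel, confirmation_db = confirmation_db)
  })
}

#' Write a protein database as FASTA
#'
#' Headers carry the lineage metadata as
#' `accession|family|EC|phylum|class|genus` with `-` for missing fields.
#'
#' @param db a ProteinRef data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_db <- function(db, path) {
  enc <- function(x) ifelse(is.na(x), "-", x)
  hdr <- sprintf("%s|%s|%s|%s|%s|%s",
                 db$accession, enc(db$family_id), enc(db$ec),
                 enc(db$phylum), enc(db$class), enc(db$genus))
  x <- Biostrings::AAStringSet(db$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a protein database written by [write_protein_db()]
#'
#' @param path FASTA file with `accession|family|EC|phylum|class|genus`
#'   headers.
#' @return a ProteinRef data.frame.
#' @export
read_protein_db <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  ## the whole header line is the record: fields may contain spaces
  parts <- strsplit(names(x), "|", fixed = TRUE)
  bad <- lengths(parts) != 6L
  if (any(bad)) stopf("malformed protein header (record %d): expected 6 '|' fields",
                      which(bad)[1])
  dec <- function(i) {
    v <- vapply(parts, `[[`, "", i)
    ifelse(v == "-", NA_character_, v)
  }
  protein_ref_table(
    accession = dec(1), description = dec(1), family_id = dec(2), ec = dec(3),
    phylum = dec(4), class = dec(5), genus = dec(6),
    sequence = as.character(x)
  )
}
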