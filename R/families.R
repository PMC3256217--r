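## Phylum/class groups used for taxonomic aggregation, with a representative
## genus for each. "Eukaryotes", "synthetic construct" and
## "uncultured/unclassified" are legal catch-all groups seen in best-hit
## annotation of public protein databases.
GROUP_INFO <- data.frame(
  group  = c("Acidobacteria", "Actinobacteria", "Alphaproteobacteria",
             "Betaproteobacteria", "Gammaproteobacteria",
             "Deltaproteobacteria", "Firmicutes", "Chloroflexi",
             "Planctomycetes", "Bacteroidetes", "Deinococcus-Thermus",
             "Gemmatimonadetes", "Eukaryotes", "synthetic construct",
             "uncultured/unclassified"),
  phylum = c("Acidobacteria", "Actinobacteria", "Proteobacteria",
             "Proteobacteria", "Proteobacteria", "Proteobacteria",
             "Firmicutes", "Chloroflexi", "Planctomycetes", "Bacteroidetes",
             "Deinococcus-Thermus", "Gemmatimonadetes", "Eukaryotes",
             "synthetic construct", "uncultured/unclassified"),
  class  = c(NA, NA, "Alphaproteobacteria", "Betaproteobacteria",
             "Gammaproteobacteria", "Deltaproteobacteria",
             NA, NA, NA, NA, NA, NA, NA, NA, NA),
  genus  = c("Solibacter", "Rhodococcus", "Sphingomonas", "Burkholderia",
             "Pseudomonas", "Sorangium", "Bacillus", "Chloroflexus",
             "Planctomyces", "Flavobacterium", "Deinococcus",
             "Gemmatimonas", NA, NA, NA),
  stringsAsFactors = FALSE
)

## group label -> phylum/class/genus
group_lineage <- function(group) {
  i <- match(group, GROUP_INFO$group)
  if (anyNA(i)) stopf("unknown taxon group: %s", group[which(is.na(i))[1]])
  GROUP_INFO[i, c("phylum", "class", "genus")]
}

## phylum (+class) -> reporting group: class for Proteobacteria, else phylum
lineage_group <- function(phylum, class) {
  ifelse(phylum == "Proteobacteria" & !is.na(class), class, phylum)
}

## The eight target gene families: membrane alkane hydroxylase (alkB),
## cytochrome P450 alkane hydroxylase (CYP153), and six aromatic
## ring-cleavage dioxygenases. C23O additionally accepts two closely
## related extradiol dioxygenase families as confirmation synonyms.
FAMILY_INFO <- data.frame(
  family_id = c("alkB", "CYP153", "P34O", "C12O", "GDO", "HGO", "C23O", "P45O"),
  name = c("alkane 1-monooxygenase",
           "cytochrome P450 alkane hydroxylase CYP153",
           "protocatechuate 3,4-dioxygenase",
           "catechol 1,2-dioxygenase",
           "gentisate 1,2-dioxygenase",
           "homogentisate 1,2-dioxygenase",
           "catechol 2,3-dioxygenase",
           "protocatechuate 4,5-dioxygenase"),
  ec = c("1.14.15.3", "1.14.-.-", "1.13.11.3", "1.13.11.1",
         "1.13.11.4", "1.13.11.5", "1.13.11.2", "1.13.11.8"),
  protein_length = c(400L, 450L, 220L, 310L, 350L, 440L, 310L, 290L),
  stringsAsFactors = FALSE
)

## Synonym families: recruited by C23O references and accepted at
## confirmation (closely related extradiol dioxygenases).
SYNONYM_INFO <- data.frame(
  family_id = c("BphC", "NahC"),
  name = c("biphenyl-2,3-diol 1,2-dioxygenase",
           "1,2-dihydroxynaphthalene dioxygenase"),
  ec = c("1.13.11.39", "1.13.11.-"),
  synonym_of = c("C23O", "C23O"),
  protein_length = c(300L, 300L),
  stringsAsFactors = FALSE
)

#' Family-synonym map for confirmation
#'
#' For each recruiting family, the set of family labels accepted at the
#' confirmation stage. Catechol 2,3-dioxygenase additionally accepts
#' biphenyl-2,3-diol 1,2-dioxygenase (EC 1.13.11.39) and
#' 1,2-dihydroxynaphthalene dioxygenase (EC 1.13.11.-), which are closely
#' related extradiol dioxygenases.
#'
#' @return named list: family id -> accepted family ids.
#' @export
default_synonym_map <- function() {
  m <- as.list(setNames(FAMILY_INFO$family_id, FAMILY_INFO$family_id))
  m[["C23O"]] <- c("C23O", "BphC", "NahC")
  m
}

## Default planted gene loads for the synthetic biopile time course:
## expected confirmed-read counts per (family, group, sample), patterned on
## a diesel-contaminated Arctic biopile — Gammaproteobacteria-dominated
## alkB at t0/t1m, Actinobacteria/Alphaproteobacteria-dominated at t1y,
## about a tenth of the load in the uncontaminated control.
## Columns: family, group, uncont, t0, t1m, t1y.
timecourse_loads <- function() {
  L <- function(family, group, uncont, t0, t1m, t1y) {
    data.frame(family_id = family, group = group, uncont = uncont,
               t0 = t0, t1m = t1m, t1y = t1y, stringsAsFactors = FALSE)
  }
  rbind(
    L("alkB", "Actinobacteria",          2, 12, 1, 22),
    L("alkB", "Alphaproteobacteria",     3, 12, 0, 14),
    L("alkB", "Betaproteobacteria",      0,  1, 0,  0),
    L("alkB", "Gammaproteobacteria",     1, 22, 9,  7),
    L("alkB", "Firmicutes",              0,  0, 0,  1),
    L("alkB", "Eukaryotes",              0,  0, 1,  0),
    L("alkB", "synthetic construct",     0,  1, 2,  1),
    L("alkB", "uncultured/unclassified", 1,  7, 4,  4),

    L("CYP153", "Acidobacteria",          1,  0,  0,  0),
    L("CYP153", "Actinobacteria",        34, 51, 15, 50),
    L("CYP153", "Alphaproteobacteria",   26, 26,  2, 20),
    L("CYP153", "Betaproteobacteria",     2,  4,  0,  1),
    L("CYP153", "Gammaproteobacteria",    1,  5,  1,  4),
    L("CYP153", "Deltaproteobacteria",    6,  2,  0,  0),
    L("CYP153", "Chloroflexi",            6,  0,  1,  0),
    L("CYP153", "Firmicutes",             2,  0,  0,  0),
    L("CYP153", "Planctomycetes",         0,  0,  0,  1),
    L("CYP153", "Eukaryotes",             0,  1,  0,  0),
    L("CYP153", "uncultured/unclassified", 3,  6,  2, 14),

    L("C23O", "Actinobacteria",          2, 1, 1, 2),
    L("C23O", "Alphaproteobacteria",     1, 5, 0, 2),
    L("C23O", "Betaproteobacteria",      0, 1, 0, 5),
    L("C23O", "Gammaproteobacteria",     0, 2, 3, 0),
    L("C23O", "Chloroflexi",             1, 0, 0, 0),
    L("C23O", "Deinococcus-Thermus",     2, 0, 0, 0),
    L("C23O", "Firmicutes",              3, 0, 1, 1),
    L("C23O", "uncultured/unclassified", 3, 9, 2, 5),

    L("BphC", "Actinobacteria",          1, 10, 1, 6),
    L("BphC", "Alphaproteobacteria",     3,  5, 0, 4),
    L("BphC", "Betaproteobacteria",      1,  1, 1, 1),
    L("BphC", "Gammaproteobacteria",     1,  2, 0, 2),
    L("BphC", "uncultured/unclassified", 0,  1, 1, 0),

    L("NahC", "Alphaproteobacteria",     0, 1, 0, 0),
    L("NahC", "Gammaproteobacteria",     0, 1, 0, 0),

    L("P45O", "Actinobacteria",          1, 3, 0, 0),
    L("P45O", "Alphaproteobacteria",     0, 5, 1, 1),
    L("P45O", "Betaproteobacteria",      0, 5, 0, 1),
    L("P45O", "Gammaproteobacteria",     1, 2, 0, 0),

    L("C12O", "Actinobacteria",          2,  7, 1, 3),
    L("C12O", "Alphaproteobacteria",     1,  7, 1, 5),
    L("C12O", "Betaproteobacteria",      2,  6, 0, 7),
    L("C12O", "Gammaproteobacteria",     1, 12, 2, 5),
    L("C12O", "Bacteroidetes",           1,  0, 0, 0),
    L("C12O", "uncultured/unclassified", 0,  3, 0, 2),

    L("P34O", "Actinobacteria",          6, 11, 5, 3),
    L("P34O", "Alphaproteobacteria",     5,  1, 1, 1),
    L("P34O", "Betaproteobacteria",      8,  2, 1, 1),
    L("P34O", "Gammaproteobacteria",     5, 15, 4, 2),
    L("P34O", "Eukaryotes",              0,  0, 0, 1),
    L("P34O", "uncultured/unclassified", 5,  0, 1, 0),

    L("GDO", "Actinobacteria",           0, 3, 2, 2),
    L("GDO", "Alphaproteobacteria",      4, 3, 0, 2),
    L("GDO", "Betaproteobacteria",       9, 8, 2, 6),
    L("GDO", "Gammaproteobacteria",      3, 0, 0, 0),

    L("HGO", "Acidobacteria",            3,  0, 0,  1),
    L("HGO", "Actinobacteria",           2,  1, 0,  0),
    L("HGO", "Alphaproteobacteria",      8, 15, 0, 13),
    L("HGO", "Betaproteobacteria",       9,  4, 1,  7),
    L("HGO", "Gammaproteobacteria",      5, 29, 2, 18),
    L("HGO", "Deltaproteobacteria",      1,  0, 0,  3),
    L("HGO", "Bacteroidetes",            1,  2, 0,  0),
    L("HGO", "Chloroflexi",              3,  0, 0,  1),
    L("HGO", "Firmicutes",               2,  0, 0,  0),
    L("HGO", "Gemmatimonadetes",         1,  0, 0,  0)
  )
}

#' Default specification of the eight target gene families
#'
#' One [family_spec()] per target family. Member taxa are the phylum/class
#' groups in which each family occurs in the default time-course design.
#'
#' @param n_reference_proteins reference proteins per family in the search
#'   panel (default 2: one Gram-positive, one Gram-negative lineage).
#' @return list of `family_spec` objects.
#' @export
default_family_specs <- function(n_reference_proteins = 2L) {
  loads <- timecourse_loads()
  lapply(seq_len(nrow(FAMILY_INFO)), function(i) {
    fi <- FAMILY_INFO[i, ]
    groups <- unique(loads$group[loads$family_id == fi$family_id])
    family_spec(
      family_id = fi$family_id, name = fi$name, ec = fi$ec,
      protein_length = fi$protein_length,
      n_reference_proteins = n_reference_proteins,
      member_groups = groups
    )
  })
}

#' Specify a gene family for the synthetic reference panel
#'
#' @param family_id unique family label.
#' @param name descriptive enzyme name.
#' @param ec primary EC number.
#' @param protein_length residues (>= 100).
#' @param n_reference_proteins reference proteins in the search panel (>= 1).
#' @param member_groups phylum/class groups carrying the family (see
#'   `petromine:::GROUP_INFO` for legal labels).
#' @return an object of class `family_spec`.
#' @export
family_spec <- function(family_id, name = family_id, ec = NA_character_,
                        protein_length = 300L, n_reference_proteins = 2L,
                        member_groups = "Gammaproteobacteria") {
  if (protein_length < 100L) stopf("protein_length must be >= 100 residues")
  if (n_reference_proteins < 1L) stopf("n_reference_proteins must be >= 1")
  structure(
    list(family_id = family_id, name = name, ec = ec,
         protein_length = as.integer(protein_length),
         n_reference_proteins = as.integer(n_reference_proteins),
         member_groups = member_groups),
    class = "family_spec"
  )
}
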