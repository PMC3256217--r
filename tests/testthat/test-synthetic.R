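test_that("reference panel has the specified structure", {
  p <- fix_panel()
  # 8 families x 2 references
  expect_equal(nrow(p$panel), 16L)
  expect_equal(sort(unique(p$panel$family_id)),
               sort(c("alkB", "CYP153", "P34O", "C12O", "GDO", "HGO",
                      "C23O", "P45O")))
  # confirmation db is a superset of the panel with decoys and synonyms
  expect_true(all(p$panel$accession %in% p$confirmation_db$accession))
  expect_gte(nrow(p$confirmation_db), 20L)
  decoys <- p$confirmation_db[is.na(p$confirmation_db$family_id), ]
  expect_gte(nrow(decoys) / nrow(p$confirmation_db), 0.20)
  expect_true(all(c("BphC", "NahC") %in% p$confirmation_db$family_id))
  # lineage invariant: class only under Proteobacteria
  with_class <- p$confirmation_db[!is.na(p$confirmation_db$class), ]
  expect_true(all(with_class$phylum == "Proteobacteria"))
})

test_that("panel generation is deterministic and rejects duplicate families", {
  f1 <- tempfile(); f2 <- tempfile()
  write_protein_db(generate_reference_panel(seed = 3)$confirmation_db, f1)
  write_protein_db(generate_reference_panel(seed = 3)$confirmation_db, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  specs <- default_family_specs()[c(1, 1)]
  expect_error(generate_reference_panel(specs), "duplicate family_id")
})

test_that("protein FASTA round-trips lineage metadata", {
  p <- fix_panel()
  f <- tempfile(fileext = ".faa")
  write_protein_db(p$confirmation_db, f)
  back <- read_protein_db(f)
  expect_equal(back$accession, p$confirmation_db$accession)
  expect_equal(back$family_id, p$confirmation_db$family_id)
  expect_equal(back$phylum, p$confirmation_db$phylum)
  expect_equal(back$class, p$confirmation_db$class)
  expect_equal(back$sequence, p$confirmation_db$sequence)
})

test_that("family members are related and decoys are not", {
  p <- fix_panel()
  db <- p$confirmation_db
  scheme <- scoring_scheme()
  global_identity <- function(a, b) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = scheme$matrix, gapOpening = scheme$gap_open,
      gapExtension = scheme$gap_extend)
    Biostrings::nmatch(pa) / Biostrings::nchar(pa)
  }
  withr::with_seed(8, {
    # within-family identity >= 60%
    for (fam in c("alkB", "C23O", "HGO")) {
      mem <- db$sequence[!is.na(db$family_id) & db$family_id == fam]
      pick <- sample(length(mem), min(3, length(mem)))
      for (i in pick) for (j in pick) if (i < j) {
        expect_gte(global_identity(mem[i], mem[j]), 0.60)
      }
    }
    # every decoy vs a sample of family members: identity < 25%
    decoys <- db$sequence[is.na(db$family_id)]
    members <- db$sequence[!is.na(db$family_id)]
    for (d in decoys) {
      for (m in sample(members, 5)) {
        expect_lt(global_identity(d, m), 0.25)
      }
    }
  })
})

test_that("metagenome generation validates its preconditions", {
  p <- fix_panel()
  expect_error(metagenome_spec("s", 0), "positive")
  expect_error(metagenome_spec("s", 10, duplicate_rate = 1), "duplicate_rate")
  expect_error(metagenome_spec("s", 10,
                               taxon_abundances = c(A = 0.5, B = 0.6)),
               "sum to 1")
  over <- metagenome_spec("s", 20, planted_gene_load = data.frame(
    family_id = "alkB", group = "Gammaproteobacteria", expected = 200),
    seed = 1)
  expect_error(generate_metagenome(over, p$confirmation_db), "exceeds")
  bad <- metagenome_spec("s", 500, planted_gene_load = data.frame(
    family_id = "alkB", group = "Planctomycetes", expected = 3), seed = 1)
  expect_error(generate_metagenome(bad, p$confirmation_db), "no panel protein")
})

test_that("truth table is complete and consistent with the dataset", {
  fx <- fix_sample()
  mg <- fx$mg
  expect_equal(nrow(mg$truth), length(mg$dataset))
  expect_equal(mg$truth$read_id, names(mg$dataset$reads))
  # duplicate_rate 0 gives zero artificial replicates
  p <- fix_panel()
  spec0 <- metagenome_spec("s", 300, duplicate_rate = 0, seed = 5)
  mg0 <- generate_metagenome(spec0, p$confirmation_db)
  expect_equal(sum(mg0$truth$is_artificial_replicate), 0L)
})

test_that("planted read counts are Poisson-consistent with the load", {
  p <- fix_panel()
  spec <- metagenome_spec("s", 5000, planted_gene_load = data.frame(
    family_id = "alkB", group = "Gammaproteobacteria", expected = 20),
    duplicate_rate = 0, seed = 11)
  mg <- generate_metagenome(spec, p$confirmation_db)
  n_planted <- sum(mg$truth$planted_family %in% "alkB")
  expect_lt(abs(n_planted - 20), 3 * sqrt(20))
})

test_that("planted fragments are recoverable at zero mutation", {
  p <- fix_panel()
  spec <- metagenome_spec("s", 120, read_length_mean = 250,
                          planted_gene_load = data.frame(
                            family_id = "C12O", group = "Betaproteobacteria",
                            expected = 8),
                          mutation_rate = 0, duplicate_rate = 0, seed = 13)
  mg <- generate_metagenome(spec, p$confirmation_db)
  planted <- which(mg$truth$planted_family %in% "C12O")
  expect_gt(length(planted), 0)
  for (i in planted) {
    src <- mg$truth$source_accession[i]
    prot <- p$confirmation_db[p$confirmation_db$accession == src, ]
    hits <- search_read(mg$dataset$reads[i], prot, e_max = Inf)
    expect_gte(nrow(hits), 1L)
    expect_gte(hits$identity[1], 0.95)
  }
})

test_that("time course defaults scale the published-size datasets", {
  tc <- fix_timecourse_run()$tc
  expect_named(tc, c("uncont", "t0", "t1m", "t1y"))
  expect_equal(length(tc$t1m$dataset), 1082L)   # 108,203 x 0.01
  expect_equal(length(tc$uncont$dataset), 4578L)
  expect_error(generate_timecourse(fix_panel()$confirmation_db, scale = 0),
               "positive")
})

test_that("time-course seeds reproduce identical datasets", {
  p <- fix_panel()
  a <- generate_timecourse(p$confirmation_db, seed = 4, scale = 0.002)
  b <- generate_timecourse(p$confirmation_db, seed = 4, scale = 0.002)
  for (s in names(a)) {
    expect_identical(as.character(a[[s]]$dataset$reads),
                     as.character(b[[s]]$dataset$reads))
    expect_identical(a[[s]]$truth, b[[s]]$truth)
  }
})

test_that("uncontaminated alkB load is about a tenth of t0", {
  tr <- fix_timecourse_run()
  n_alkB <- function(s) sum(tr$truth[[s]]$planted_family %in% "alkB" &
                              !tr$truth[[s]]$is_artificial_replicate)
  ratio <- n_alkB("uncont") / n_alkB("t0")
  expect_gt(ratio, 0.02)
  expect_lt(ratio, 0.35)
})
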