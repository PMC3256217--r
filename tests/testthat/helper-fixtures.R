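## Shared fixtures, built lazily and cached for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

## default synthetic panel + confirmation database, seed 7
fix_panel <- function() cached("panel", generate_reference_panel(seed = 7))

## one small sample with 17 planted alkB reads (the t1m-style scenario)
fix_sample <- function() cached("sample", {
  p <- fix_panel()
  spec <- metagenome_spec(
    "t1m", 2000, read_length_mean = 327, read_length_sd = 50,
    duplicate_rate = 0.1,
    planted_gene_load = data.frame(family_id = "alkB",
                                   group = "Gammaproteobacteria",
                                   expected = 20),
    mutation_rate = 0.02, seed = 11
  )
  mg <- generate_metagenome(spec, p$confirmation_db)
  derep <- remove_artificial_replicates(mg$dataset)
  rec <- recruit(derep$dataset, p$panel)
  conf <- confirm(rec, derep$dataset, p$confirmation_db)
  list(mg = mg, derep = derep, records = conf)
})

## the four-sample time course at desk scale with the full mining run and
## both normalizations; expensive (about two minutes), shared across tests
fix_timecourse_run <- function() cached("tc_run", {
  p <- fix_panel()
  tc <- generate_timecourse(p$confirmation_db, seed = 1, scale = 0.01)
  clean <- list(); truth <- list(); records <- list()
  for (s in names(tc)) {
    clean[[s]] <- remove_artificial_replicates(tc[[s]]$dataset)$dataset
    truth[[s]] <- tc[[s]]$truth
    rec <- recruit(clean[[s]], p$panel)
    records[[s]] <- confirm(rec, clean[[s]], p$confirmation_db)
  }
  records <- data.table::rbindlist(records, fill = TRUE)
  n_reads <- vapply(clean, length, 0L)
  per100 <- normalize_abundance(aggregate_counts(records), n_reads)
  totals <- table_totals(per100)
  subcounts <- data.table::rbindlist(lapply(names(clean), function(s) {
    suppressWarnings(normalize_by_subsampling(
      clean[[s]], p$panel, p$confirmation_db, n = 1000, seed = 2))
  }))
  conc <- concordance(totals, subcounts)
  list(tc = tc, clean = clean, truth = truth, records = records,
       per100 = per100, totals = totals, subcounts = subcounts, conc = conc)
})
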