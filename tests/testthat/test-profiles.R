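test_that("per-100-genomes normalization reproduces the unit increments", {
  expect_equal(normalize_per_100_genomes(9, 108203), 62.4)
  expect_equal(normalize_per_100_genomes(1, 457781), 1.6)
  expect_equal(normalize_per_100_genomes(1, 364725), 2.1)
  expect_equal(normalize_per_100_genomes(1, 287705), 2.6)
  expect_equal(normalize_per_100_genomes(1, 108203), 6.9)
  expect_equal(normalize_per_100_genomes(0, 108203), 0.0)
  # the unit definition: one hit in 750,000 reads is 1.0 per 100 genomes
  expect_equal(normalize_per_100_genomes(1, 750000), 1.0)
  expect_error(normalize_per_100_genomes(1, 0), "positive")
  expect_error(normalize_per_100_genomes(-1, 100), "non-negative")
})

test_that("normalization is linear in the raw count before rounding", {
  for (k in c(1, 3, 10)) {
    unrounded <- k * 750000 / 364725
    expect_equal(normalize_per_100_genomes(k, 364725),
                 round_half_up(unrounded, 1))
    expect_equal(2 * unrounded, (2 * k) * 750000 / 364725)
  }
})

test_that("totals are sums of rounded per-group values", {
  tab <- data.frame(
    family_id = "alkB", sample_id = "t1m",
    group = c("Actinobacteria", "Gammaproteobacteria", "Eukaryotes",
              "synthetic construct", "uncultured/unclassified"),
    raw_count = c(1L, 9L, 1L, 2L, 4L),
    n_reads = 108203,
    per100 = c(6.9, 62.4, 6.9, 13.9, 27.7)
  )
  tt <- table_totals(tab)
  expect_equal(tt$total_per100, 117.8)
  # equal to 17 hits normalized directly in this case
  expect_equal(normalize_per_100_genomes(17, 108203), 117.8)
  # a second published pattern
  tab2 <- data.frame(family_id = "alkB", sample_id = "t1y",
                     group = letters[1:6], raw_count = 1L, n_reads = 287705,
                     per100 = c(57.3, 36.5, 18.2, 2.6, 2.6, 10.4))
  expect_equal(table_totals(tab2)$total_per100, 127.6)
  # single-group family: total equals the group value
  tab3 <- data.frame(family_id = "GDO", sample_id = "t0", group = "x",
                     raw_count = 2L, n_reads = 364725, per100 = 4.1)
  expect_equal(table_totals(tab3)$total_per100, 4.1)
})

test_that("normalize_abundance joins dataset sizes per sample", {
  counts <- data.frame(family_id = "alkB", group = "Gammaproteobacteria",
                       sample_id = c("t0", "t1m"), raw_count = c(22L, 9L))
  out <- normalize_abundance(counts, c(t0 = 364725, t1m = 108203))
  expect_equal(out$per100, c(45.2, 62.4))
  expect_error(normalize_abundance(counts, c(t0 = 364725)), "no dataset size")
})

test_that("internal Spearman agrees with the reference implementation", {
  withr::with_seed(61, {
    for (rep in 1:20) {
      x <- sample(0:10, 12, replace = TRUE)  # ties included
      y <- x + sample(-3:3, 12, replace = TRUE)
      expect_equal(petromine:::spearman_rho(x, y),
                   suppressWarnings(cor(x, y, method = "spearman")),
                   tolerance = 1e-12)
    }
  })
})

test_that("concordance handles identity, reversal and degenerate input", {
  a <- data.frame(family_id = letters[1:6], sample_id = "s",
                  total_per100 = c(1.5, 3.2, 7.8, 0.4, 9.9, 5.5))
  b_same <- data.frame(family_id = letters[1:6], sample_id = "s",
                       raw_count = c(2, 4, 8, 1, 12, 6))
  expect_equal(concordance(a, b_same)$rho, 1.0)
  b_rev <- data.frame(family_id = letters[1:6], sample_id = "s",
                      raw_count = 13 - c(2, 4, 8, 1, 12, 6))
  expect_equal(concordance(a, b_rev)$rho, -1.0)
  expect_error(concordance(a[1:3, ], b_same[1:3, ]), "at least 5")
  # exact permutation p-value for a perfect small ranking
  ex <- concordance(a, b_same, method = "exact")
  expect_equal(ex$rho, 1.0)
  expect_equal(ex$p_value, 2 / factorial(6), tolerance = 1e-12)
})

test_that("subsampling normalization at full size equals the full run", {
  p <- fix_panel()
  fx <- fix_sample()
  d <- fx$derep$dataset
  full <- aggregate_counts(fx$records)
  full_fam <- full[, .(raw_count = sum(raw_count)),
                   by = c("family_id", "sample_id")]
  sub <- normalize_by_subsampling(d, p$panel, p$confirmation_db,
                                  n = length(d), seed = 3)
  m <- merge(as.data.frame(full_fam), as.data.frame(sub),
             by = c("family_id", "sample_id"), all = TRUE)
  expect_equal(m$raw_count.x, m$raw_count.y)
  # oversized request falls back to the full dataset with a warning
  expect_warning(
    sub2 <- normalize_by_subsampling(d, p$panel, p$confirmation_db,
                                     n = length(d) + 10, seed = 3),
    "exceeds")
  expect_equal(sort(sub2$raw_count), sort(sub$raw_count))
})

test_that("genome-size correction divides fragment counts by genome size", {
  p <- fix_panel()
  two <- p$confirmation_db[!is.na(p$confirmation_db$family_id), ][c(1, 20), ]
  gdb <- data.frame(two, organism = c("orgA", "orgB"),
                    genome_size = c(3e6, 6e6))
  withr::with_seed(67, {
    reads <- c(
      vapply(1:10, function(i) {
        cds <- petromine:::reverse_translate(gdb$sequence[1])
        substr(cds, 1, 200)
      }, ""),
      vapply(1:10, function(i) {
        cds <- petromine:::reverse_translate(gdb$sequence[2])
        substr(cds, 1, 200)
      }, "")
    )
  })
  d <- mg_dataset(sprintf("r%02d", 1:20), reads)
  prof <- taxon_profile(d, gdb)
  expect_equal(prof$fragment_count, c(10L, 10L))
  # equal counts, double genome size -> half the corrected abundance
  expect_equal(prof$corrected_abundance[1] / prof$corrected_abundance[2], 2)
  expect_equal(prof$fraction, c(2 / 3, 1 / 3))
  expect_equal(sum(prof$fraction), 1)
})

test_that("short alignments are excluded by the 50 bp rule", {
  p <- fix_panel()
  one <- p$confirmation_db[!is.na(p$confirmation_db$family_id), ][1, ]
  gdb <- data.frame(one, organism = "orgA", genome_size = 3e6)
  withr::with_seed(71, {
    cds <- petromine:::reverse_translate(one$sequence)
    # 48 bp in-frame fragment: E-value passes but the span is < 50 bp
    short <- substr(cds, 1, 48)
    long <- substr(cds, 1, 150)
    d <- mg_dataset(c("short1", "long1"), c(short, long))
  })
  prof <- taxon_profile(d, gdb, e_max = Inf)
  expect_equal(prof$fragment_count, 1L)
  # genomes without a size are excluded with a warning
  gdb2 <- rbind(gdb, data.frame(one[, ], organism = "orgB",
                                genome_size = NA))
  gdb2$accession[2] <- "OTHER_01"
  expect_warning(taxon_profile(d, gdb2, e_max = Inf), "without size")
})

test_that("planted organism mixtures are recovered by the taxon profile", {
  p <- fix_panel()
  two <- p$confirmation_db[!is.na(p$confirmation_db$family_id), ][c(3, 25), ]
  gdb <- data.frame(two, organism = c("orgA", "orgB"), genome_size = 3e6)
  n <- 60
  withr::with_seed(73, {
    pick <- rbinom(n, 1, 0.3) + 1L  # 70% orgA, 30% orgB
    reads <- vapply(seq_len(n), function(i) {
      cds <- petromine:::reverse_translate(gdb$sequence[pick[i]])
      start <- sample(nchar(cds) - 180, 1)
      substr(cds, start, start + 179)
    }, "")
  })
  d <- mg_dataset(sprintf("mix%03d", seq_len(n)), reads)
  prof <- taxon_profile(d, gdb)
  p_a <- prof$fraction[prof$organism == "orgA"]
  sigma <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(p_a - 0.7), 3 * sigma + 0.02)
})
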