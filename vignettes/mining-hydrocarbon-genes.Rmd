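---
title: "Mining hydrocarbon-degradation genes from shotgun metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining hydrocarbon-degradation genes from shotgun metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diesel is a mixture of aliphatic and aromatic hydrocarbons, and its
microbial degradation in soil runs through a small set of well-known
enzyme families: the membrane alkane hydroxylase (*alkB*) and the CYP153
cytochrome P450 for alkanes, and the intradiol, extradiol and
gentisate/homogentisate ring-cleavage dioxygenases for aromatics. In a
shotgun metagenome of a contaminated soil, the abundance of reads matching
these families — and the taxa those reads point to — tells you who can
degrade what, without culturing or PCR bias.

petromine re-implements, as a tested and reusable pipeline, the classic
454-era workflow for this question:

1. **Dereplication.** Pyrosequencing emits *artificial replicates* —
   multiple reads of one template sharing the same 5' start, often with 3'
   truncation. Reads whose leading bases match and whose identity over the
   shorter read exceeds a threshold are clustered and only the longest
   representative is kept (`remove_artificial_replicates()`).
2. **Recruitment.** Every read is compared in six-frame translation against
   a small reference panel (two reference proteins per family, one
   Gram-positive and one Gram-negative lineage where available). Any
   (read, family) pair reaching E < 0.10 is *recruited*
   (`recruit()`). The threshold is deliberately permissive so fragments
   from distantly related organisms are not missed.
3. **Confirmation.** Each recruited read is searched against a broad
   confirmation database (family members across many taxa, closely related
   synonym families, unrelated proteins) and its single best hit decides:
   if the best hit belongs to the recruiting family — or, for catechol
   2,3-dioxygenase, to the closely related biphenyl-2,3-diol
   1,2-dioxygenase (EC 1.13.11.39) or 1,2-dihydroxynaphthalene dioxygenase
   (EC 1.13.11.-) — the read is confirmed, otherwise discarded
   (`confirm()`). The best hit's lineage supplies the taxonomic label,
   kept deliberately coarse (phylum, or class for Proteobacteria) because
   these catabolic genes often ride on plasmids and finer placement of a
   ~350 bp fragment is not reliable.
4. **Normalization.** Confirmed counts are scaled to 100 genome
   equivalents, and independently re-estimated by re-running the mining on
   a fixed-size random subsample; the rank concordance of the two
   normalizations is reported (`normalize_per_100_genomes()`,
   `normalize_by_subsampling()`, `concordance()`).
5. **Genome-size-corrected taxonomic profiles** (`taxon_profile()`) and
   **spike-corrected qPCR quantification** (`analyze_qpcr()`) round out the
   analysis.

## The alignment engine and its statistics

The engine is affine-gap Smith–Waterman over six-frame translations,
delegated to the Biostrings C implementation behind `local_align()`.
Defaults are BLOSUM62 with gap open 11 / extend 1, and raw scores are
converted with the standard gapped Karlin–Altschul constants
(lambda = 0.267 nats, K = 0.041):

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad
  E = m \, n \, 2^{-S'}$$

with *m* the longest frame translation of the read (residues) and *n* the
total residue count of the database searched. Three numerical choices
matter:

* **Stop codons break alignments.** Frame translations are split at `*`
  and segments aligned independently; a real coding fragment has an open
  frame, and allowing alignments across stops would reward spurious
  joins.
* **Seeding.** Like BLAST itself, the search is word-seeded: only
  read/protein pairs sharing an exact amino-acid 5-mer go to full
  Smith–Waterman. For planted fragments at the mutation rates simulated
  here the seeded and exhaustive searches give identical best hits (this
  equivalence is tested); what seeding can miss is only chance similarity
  near the permissive threshold, which the confirmation stage discards
  anyway. `use_seeds = FALSE` gives the exhaustive search.
* **No edge-effect correction** of *m* and *n*: the thresholds this
  pipeline uses (0.10 and 1e-5) sit far from where that correction makes a
  difference at these sequence lengths.

E-values depend on database size, so the same alignment is "significant"
against a small panel and insignificant against a large one; recruitment
E-values here are computed on the read-versus-panel search space. The
direction of the comparison (reads as queries against the panel) is the
transpose of screening references against a read database; the optimal
local alignment score is symmetric, so only the E-value scale differs, and
all thresholds are interpreted on the read-versus-panel scale.

## Normalization conventions

Counts are normalized per 100 genome equivalents assuming 3 Mbp genomes
and 400 bp reads: 100 × 3 Mbp = 300 Mbp ≙ 750,000 reads, so

```
per100 = round(raw_count * 750000 / n_reads, 1 decimal)
```

with `n_reads` the *post-dereplication* read count and rounding half away
from zero. Dividing by read count (not base count) is what makes
single-hit increments across datasets of different sizes come out as the
characteristic values 1.6, 2.1, 6.9 and 2.6 for the four default dataset
sizes. Per-family totals are sums of the rounded per-group values — the
convention that reproduces published tables of this kind, where a total
row may correspond to no integer hit count.

The Spearman statistic in `concordance()` is computed directly (average
ranks, Pearson on ranks) rather than through a library call, with the
large-sample t approximation for P; an exact permutation P-value is
available below ten pairs (enumeration is capped at eight).

## What the synthetic data emulate — and what they do not

`generate_timecourse()` emulates four pooled 454 datasets from a
bioremediation biopile time course (uncontaminated control, freshly
contaminated t0, one month t1m, one year t1y), with read counts
457,781 / 364,725 / 108,203 / 287,705 scaled by a desk-scale factor
(default 0.01) and mean read lengths 441 / 343 / 327 / 350 bp (sd 50).
Design choices, made once:

* **Background reads are i.i.d. uniform nucleotides.** This guarantees the
  background essentially never passes E < 0.10 against a desk-scale panel,
  so planted truth is recoverable. Real soil metagenomes have composition
  structure, homopolymer errors and real genes; passing tests here shows
  the machinery is correct, not that real-data sensitivity equals the
  synthetic one.
* **Planted fragments** are reverse-translated from confirmation-database
  proteins with uniform random synonymous codons (composition-neutral, no
  codon-bias artifact), placed on a random strand, substituted at 2% per
  base by default, and at least 150 bp so they stay recoverable.
* **Planted loads** are expected confirmed-read counts per (family, taxon
  group, sample), patterned on the per-sample hit counts back-derived from
  the published per-100-genomes tables of the emulated study:
  Gammaproteobacteria-dominated *alkB* at t0/t1m shifting to
  Actinobacteria/Alphaproteobacteria at t1y, and about a tenth of the load
  in the uncontaminated control. Loads are absolute counts, *not*
  multiplied by the scale factor: subsampling `100000 * scale` reads then
  reproduces the full-scale counting regime (same expected subsample
  counts), which is what makes the desk-scale concordance statistic
  comparable to the full-scale one.
* **Artificial replicates** are exact copies with optional 3' truncation
  (the same-start 454 artifact), appended until the requested fraction of
  emitted reads are replicates.
* **Synthetic proteins**: each family descends from one random ancestor
  (members at ~12% divergence, so within-family identity stays above 60%);
  the two C23O synonym families descend from the C23O ancestor at ~18%
  divergence; decoys are independent random proteins (global identity to
  any family member far below 25%). Biological replicates of the pooled
  samples are not simulated — no per-replicate sequence characteristics
  are available to calibrate them.

The qPCR generator simulates ten-fold dilution standards
(`Ct = intercept − log10(copies)/log10(1+efficiency)` plus Gaussian noise,
default sd 0.1 Ct), triplicate wells as on a real rotor, per-sample PCR
inhibition acting multiplicatively on template, and lambda spikes at 1e5
copies/µl whose measured recovery quantifies that inhibition. Correction
divides by recovery only when recovery is below 100% — over-recovery never
deflates a quantification. Inhibition defaults span the 6–45% range
reported for soil RNA extracts.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `recruit_e` | 0.10 | recruitment E-value ceiling (permissive on purpose) |
| `annotate_e` | 1e-5 | best-hit annotation ceiling for taxon profiles |
| `min_aln_bp` | 50 bp | minimum alignment span on the read for annotation |
| `weak_e` | 1e-30 | diagnostic split: recruits above this rarely confirm |
| `subsample_n` | 100,000 | subsampling-normalization size (× scale) |
| `prefix_len` | 3 bp | identical 5' bases defining a replicate candidate |
| `identity_threshold` | 0.90 | identity over the shorter read for replicates |
| gap open/extend | 11 / 1 | affine gap penalties (BLOSUM62) |

The dereplication parameters are the conventional ones for the same-start
454 artifact model; identity is computed over an end-free alignment of the
shorter read against the longer because replicates share a 5' start but
differ in 3' truncation. Tie-breaks everywhere are deterministic (bit
score, then E-value, then database order; longest read, then input order).
A read recruited by several families keeps the family of its best
confirmation hit, so per-family tables never double-count a read.

## Problem sizes and runtime

The package's default desk scale (0.01, i.e. ~12,000 reads across the four
samples, a ~30-protein confirmation database) runs the full pipeline —
generation, dereplication, both normalizations, concordance, taxon
profiles and qPCR — in about two minutes on one core. The same code runs
at any scale; all sizes are parameters.

## Known limitations

* Uniform-random background underestimates the false-recruitment rate of
  real metagenomes; the confirmation stage bears that load in practice,
  and its discrimination power grows with confirmation-database breadth.
  At desk scale a small number of chance recruits can be "confirmed"
  because the panel is a subset of the confirmation database; measured
  taxon-group precision on the synthetic truth stays above 0.95.
* 454 homopolymer errors, quality scores and chimeras are not simulated;
  no quality trimming is implemented.
* E-values use raw m×n search spaces (no length correction), and
  low-complexity masking is off.
* The genus-level roll-up is reported but intentionally secondary to the
  phylum/class aggregation.

## A short run

```r
library(petromine)
p <- generate_reference_panel(seed = 7)
tc <- generate_timecourse(p$confirmation_db, seed = 1, scale = 0.01)
d <- remove_artificial_replicates(tc$t1m$dataset)$dataset
rec <- recruit(d, p$panel)
conf <- confirm(rec, d, p$confirmation_db)
counts <- aggregate_counts(conf)
normalize_abundance(counts, setNames(length(d), "t1m"))
```

or, end to end from one config: `run_full(pipeline_config())`.
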