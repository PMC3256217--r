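## Independent brute-force oracle for affine-gap local alignment: memoized
## recursion over (i, j, state) enumerating every way to extend an
## alignment, with the option to terminate at any point. Exponential in
## spirit, DP by memoization; written without reference to the package's
## alignment path (which is the Biostrings C engine).
sw_brute <- function(p, s, mat, gap_open, gap_extend) {
  pa <- strsplit(p, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  n <- length(pa); m <- length(sa)
  memo <- new.env(hash = TRUE)
  ## best score of an alignment continuing from (i, j); state M = last
  ## column was a match/mismatch, P/S = inside a gap in pattern/subject
  ext <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- 0  # stop here
    if (i <= n && j <= m) {
      best <- max(best, mat[pa[i], sa[j]] + ext(i + 1L, j + 1L, "M"))
    }
    if (j <= m) {  # gap in pattern (consume subject)
      cost <- if (state == "P") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + ext(i, j + 1L, "P"))
    }
    if (i <= n) {  # gap in subject (consume pattern)
      cost <- if (state == "S") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + ext(i + 1L, j, "S"))
    }
    memo[[key]] <- best
    best
  }
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- max(best, mat[pa[i], sa[j]] + ext(i + 1L, j + 1L, "M"))
    }
  }
  best
}

## brute-force all-pairs replicate clustering oracle: single linkage over
## pairs that share a prefix and reach the identity threshold, identity
## computed by ungapped comparison over the shorter read (test data has no
## indels)
derep_oracle <- function(seqs, prefix_len = 3, threshold = 0.9) {
  n <- length(seqs)
  cl <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- seqs[i]; b <- seqs[j]
      if (substr(a, 1, prefix_len) != substr(b, 1, prefix_len)) next
      la <- min(nchar(a), nchar(b))
      id <- mean(strsplit(substr(a, 1, la), "")[[1]] ==
                   strsplit(substr(b, 1, la), "")[[1]])
      if (id >= threshold) cl[cl == cl[j]] <- cl[i]
    }
  }
  cl
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
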