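#' Round half away from zero
#'
#' Reported table values use commercial rounding (half away from zero), not
#' base R's round-half-even, so a raw count of 9 in 108,203 reads prints as
#' 62.4 rather than 62.3.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # small relative epsilon guards against 0.4999999 artifacts of division
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## derive a child seed from a master seed; keeps results < 2^31
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * k) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

## uniform random protein of length n
random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

## mutate a protein: substitute each residue with prob p (to a different aa)
mutate_protein <- function(seq, p) {
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(aa)) < p
  if (any(hit)) {
    aa[hit] <- vapply(aa[hit], function(a) sample(setdiff(AA20, a), 1), "")
  }
  paste(aa, collapse = "")
}
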