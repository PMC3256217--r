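#' Simulate a qPCR experiment with dilution-series standards and lambda spikes
#'
#' Generates Ct tables with known truth: ten-fold dilution-series standards
#' per target, unknown samples whose measured template is attenuated by a
#' per-sample PCR inhibition fraction, and bacteriophage lambda spikes added
#' at a known concentration (default 1e5 copies/ul) to quantify that
#' inhibition. Ct values follow
#' `Ct = intercept - log10(copies) / log10(1 + efficiency)` plus Gaussian
#' noise.
#'
#' @param true_copies named numeric (sample -> copies/ng) for a single
#'   target, or a data.frame with `sample`, `target`, `copies`.
#' @param efficiency amplification efficiency in (0, 1]; 1 is perfect
#'   doubling per cycle.
#' @param inhibition named numeric (sample -> inhibited fraction in [0, 1)).
#' @param noise_sd Gaussian Ct noise (Ct units).
#' @param seed integer seed.
#' @param intercept Ct of a single template copy (default 37).
#' @param standard_copies copy numbers of the dilution series
#'   (default 1e2..1e7).
#' @param spike_copies lambda spike input (default 1e5 copies/ul).
#' @param replicates technical replicate wells per reaction (default 3, the
#'   usual bench practice; replicate Ct values are averaged downstream).
#' @return data.frame with `sample`, `target`, `role`
#'   (standard/unknown/spike), `replicate`, `known_copies` (standards only)
#'   and `ct` — the layout [analyze_qpcr()] consumes.
#' @export
generate_qpcr_experiment <- function(true_copies, efficiency = 0.95,
                                     inhibition = NULL, noise_sd = 0.1,
                                     seed = 1L, intercept = 37,
                                     standard_copies = 10^(2:7),
                                     spike_copies = 1e5, replicates = 3L) {
  if (efficiency <= 0 || efficiency > 1) stopf("efficiency must be in (0, 1]")
  if (is.data.frame(true_copies)) {
    tc <- true_copies
  } else {
    tc <- data.frame(sample = names(true_copies), target = "target",
                     copies = as.numeric(true_copies))
  }
  if (any(tc$copies <= 0)) stopf("copy numbers must be positive")
  if (any(standard_copies <= 0)) stopf("standard copies must be positive")
  samples <- unique(tc$sample)
  if (is.null(inhibition)) inhibition <- setNames(rep(0, length(samples)), samples)
  if (any(inhibition < 0 | inhibition >= 1)) {
    stopf("inhibition must be in [0, 1)")
  }
  if (replicates < 1L) stopf("replicates must be >= 1")
  slope <- -1 / log10(1 + efficiency)
  ct_of <- function(copies) intercept + slope * log10(copies)
  wells <- function(sample, target, role, known, copies) {
    k <- length(copies)
    data.frame(
      sample = rep(sample, each = replicates),
      target = rep(target, each = replicates),
      role = role,
      replicate = rep(seq_len(replicates), k),
      known_copies = rep(known, each = replicates),
      ct = ct_of(rep(copies, each = replicates)) +
        rnorm(k * replicates, 0, noise_sd)
    )
  }

  withr::with_seed(seed, {
    rows <- list()
    for (tg in c(unique(tc$target), "lambda")) {
      rows[[length(rows) + 1L]] <- wells("std", tg, "standard",
                                         standard_copies, standard_copies)
    }
    meas <- tc$copies * (1 - inhibition[tc$sample])
    rows[[length(rows) + 1L]] <- wells(tc$sample, tc$target, "unknown",
                                       NA_real_, meas)
    spike_meas <- spike_copies * (1 - inhibition[samples])
    rows[[length(rows) + 1L]] <- wells(samples, "lambda", "spike",
                                       NA_real_, spike_meas)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct on log10(copies) over a dilution series.
#' Amplification efficiency derives from the slope as
#' `10^(-1/slope) - 1`; perfect doubling gives slope -1/log10(2), about
#' -3.32 Ct per decade.
#'
#' @param dilutions data.frame with `copies` and `ct` (at least 3 points
#'   spanning at least 2 orders of magnitude).
#' @return object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n`.
#' @export
fit_standard_curve <- function(dilutions) {
  if (any(dilutions$copies <= 0)) stopf("standard copies must be positive")
  if (nrow(dilutions) < 3L) stopf("standard curve needs at least 3 dilution points")
  lx <- log10(dilutions$copies)
  if (diff(range(lx)) < 2) {
    stopf("standards must span at least 2 orders of magnitude")
  }
  fit <- lm(ct ~ lx, data = data.frame(ct = dilutions$ct, lx = lx))
  slope <- unname(coef(fit)[2])
  r2 <- 1 - sum(residuals(fit)^2) / sum((dilutions$ct - mean(dilutions$ct))^2)
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]), r_squared = r2,
         efficiency = 10^(-1 / slope) - 1, n = nrow(dilutions)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: slope %.4f, intercept %.2f, R2 %.4f, efficiency %.1f%%\n",
              x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Absolute quantification from a Ct value
#'
#' Inverts the standard curve: `copies = 10^((ct - intercept) / slope)`.
#'
#' @param ct observed Ct value(s).
#' @param curve a [fit_standard_curve()] object.
#' @return estimated copies.
#' @export
quantify <- function(ct, curve) {
  if (curve$slope == 0) stopf("standard curve has zero slope")
  10^((ct - curve$intercept) / curve$slope)
}

#' Lambda spike recovery and PCR inhibition
#'
#' The measured recovery of a known lambda DNA spike quantifies PCR
#' inhibition by soil co-extracts. Recovery is capped at 1 for the reported
#' inhibition (over-recovery means no inhibition).
#'
#' @param measured measured spike copies.
#' @param expected spiked-in copies (default 1e5 copies/ul).
#' @return list with `recovery` (uncapped fraction) and
#'   `inhibition_percent` (`100 * max(0, 1 - recovery)`).
#' @export
spike_recovery <- function(measured, expected = 1e5) {
  if (any(measured <= 0)) stopf("measured spike copies must be positive")
  recovery <- measured / expected
  list(recovery = recovery,
       inhibition_percent = 100 * pmax(0, 1 - recovery))
}

#' Correct a quantification for PCR inhibition
#'
#' Proportional spike-in correction: when spike recovery is below 100% the
#' raw value is divided by the recovery; over-recovery leaves values
#' unchanged (quantities are only corrected upward, never deflated).
#'
#' @param raw_copies raw quantification(s).
#' @param recovery spike recovery fraction(s) (> 0).
#' @return corrected copies.
#' @export
correct_for_inhibition <- function(raw_copies, recovery) {
  if (any(recovery <= 0)) stopf("recovery must be positive")
  ifelse(recovery < 1, raw_copies / recovery, raw_copies)
}

#' Relative expression as a percentage of a total
#'
#' @param component_copies component quantification (>= 0).
#' @param total_copies total quantification (> 0).
#' @return percentage, two decimals.
#' @examples
#' relative_expression(2.0248e5, 1.26e6)  # 16.07
#' @export
relative_expression <- function(component_copies, total_copies) {
  if (any(total_copies <= 0)) stopf("total copies must be positive")
  if (any(component_copies < 0)) stopf("component copies must be non-negative")
  round_half_up(100 * component_copies / total_copies, 2)
}

#' Analyze a qPCR Ct table end to end
#'
#' For each target: fit the standard curve over all standard wells,
#' quantify the unknowns (technical replicate wells are quantified
#' individually and averaged on the copy scale), measure lambda spike
#' recovery per sample from the lambda curve, and correct all
#' quantifications for inhibition.
#'
#' @param ct_table data.frame as produced by [generate_qpcr_experiment()]
#'   or read from CSV: `sample`, `target`, `role`
#'   (standard/unknown/spike), `known_copies`, `ct` (one row per well;
#'   replicate wells simply repeat the sample/target/role).
#' @param spike_expected lambda spike input (default 1e5 copies/ul).
#' @return list with `curves` (named list of [fit_standard_curve()]
#'   results) and `results`: `sample`, `target`, `raw_copies`, `recovery`,
#'   `inhibition_percent`, `corrected_copies`.
#' @export
analyze_qpcr <- function(ct_table, spike_expected = 1e5) {
  std <- ct_table[ct_table$role == "standard", ]
  if (nrow(std) == 0L) stopf("no standards in Ct table")
  curves <- lapply(split(std, std$target), function(s) {
    fit_standard_curve(data.frame(copies = s$known_copies, ct = s$ct))
  })

  spikes <- ct_table[ct_table$role == "spike", ]
  recov <- setNames(rep(1, 0), character())
  if (nrow(spikes) > 0L) {
    if (is.null(curves[["lambda"]])) stopf("spikes present but no lambda standards")
    meas <- tapply(quantify(spikes$ct, curves[["lambda"]]), spikes$sample, mean)
    recov <- spike_recovery(as.numeric(meas), spike_expected)$recovery
    names(recov) <- names(meas)
  }

  unk <- ct_table[ct_table$role == "unknown", ]
  res <- lapply(split(unk, paste(unk$sample, unk$target, sep = "\r")), function(u) {
    curve <- curves[[u$target[1]]]
    if (is.null(curve)) stopf("no standards for target '%s'", u$target[1])
    raw <- mean(quantify(u$ct, curve))
    r <- if (u$sample[1] %in% names(recov)) recov[[u$sample[1]]] else 1
    data.frame(sample = u$sample[1], target = u$target[1], raw_copies = raw,
               recovery = r, inhibition_percent = 100 * max(0, 1 - r),
               corrected_copies = correct_for_inhibition(raw, r))
  })
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  list(curves = curves, results = results)
}
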