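# Frequency-wise paired condition comparison: one-sided paired Wilcoxon
# signed-rank tests and Benjamini-Hochberg false discovery rate control.

#' Paired per-session spectra for two conditions
#'
#' @param freqs Frequency grid in Hz.
#' @param run,baseline Numeric matrices `[n_sessions x n_freqs]`; rows are
#'   the same sessions in both conditions.
#' @return A `paired_spectra_set` object.
#' @export
paired_spectra_set <- function(freqs, run, baseline) {
  run <- as.matrix(run); baseline <- as.matrix(baseline)
  if (!all(dim(run) == dim(baseline))) {
    stopf("run and baseline must be paired (same sessions, same grid)")
  }
  if (ncol(run) != length(freqs)) stopf("column count must match the grid")
  structure(list(freqs = freqs, run = run, baseline = baseline),
            class = "paired_spectra_set")
}

#' Frequency-wise one-sided paired Wilcoxon signed-rank test
#'
#' At each frequency, tests whether the run values exceed the baseline
#' values across sessions (or the reverse). Zero differences are dropped;
#' the exact null distribution (shift algorithm, midranks under ties) is
#' used for fewer than 25 informative pairs, otherwise the normal
#' approximation with continuity correction.
#'
#' @param set A [paired_spectra_set()]. To test one condition against zero,
#'   pass a zero matrix as `baseline`.
#' @param alternative `"greater"` (run > baseline, default) or `"less"`.
#' @return Data frame with `freq_hz`, `p_raw`, `n_used` (informative pairs),
#'   and `degenerate` (`TRUE` where all differences were zero; there
#'   `p_raw = 1`).
#' @export
wilcoxon_paired <- function(set, alternative = c("greater", "less")) {
  stopifnot(inherits(set, "paired_spectra_set"))
  alternative <- match.arg(alternative)
  if (nrow(set$run) < 5) stopf("need at least 5 paired sessions")
  out <- lapply(seq_along(set$freqs), function(fi) {
    d <- set$run[, fi] - set$baseline[, fi]
    dnz <- d[d != 0]
    if (length(dnz) == 0) {
      return(data.frame(freq_hz = set$freqs[fi], p_raw = 1,
                        n_used = 0L, degenerate = TRUE))
    }
    p <- if (length(dnz) < 25) {
      .exact_signed_rank_p(dnz, alternative)
    } else {
      suppressWarnings(
        stats::wilcox.test(dnz, alternative = alternative, mu = 0,
                           exact = FALSE, correct = TRUE)$p.value)
    }
    data.frame(freq_hz = set$freqs[fi], p_raw = p, n_used = length(dnz),
               degenerate = FALSE)
  })
  do.call(rbind, out)
}

# Exact one-sided signed-rank p-value with midranks (ties allowed): the null
# assigns each sign pattern probability 2^-n; the distribution of W+ is built
# by the shift algorithm on doubled midranks (integers even under ties).
.exact_signed_rank_p <- function(d, alternative) {
  n <- length(d)
  r <- rank(abs(d))              # midranks
  m <- as.integer(round(2 * r)) # doubled -> integer weights
  w_obs <- sum(m[d > 0])
  total <- sum(m)
  counts <- numeric(total + 1)   # counts[w + 1] = #subsets with sum w
  counts[1] <- 1
  for (mi in m) {
    shifted <- c(numeric(mi), counts[seq_len(total + 1 - mi)])
    counts <- counts + shifted
  }
  probs <- counts / 2^n
  if (alternative == "greater") {
    sum(probs[(w_obs + 1):(total + 1)])
  } else {
    sum(probs[1:(w_obs + 1)])
  }
}

#' Benjamini-Hochberg FDR correction across frequencies
#'
#' Step-up procedure at level `q`: the significance mask rejects every
#' p-value at or below the adaptive threshold `p* = max{p_(i) : p_(i) <=
#' i q / m}`.
#'
#' @param pvals Raw p-values in `(0, 1]`.
#' @param q Target false discovery rate (default 0.05).
#' @return List with `mask` (logical), `threshold` (`p*`; 0 when nothing is
#'   rejected), `q`, `n_tests`, `n_significant`.
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stopf("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  m <- length(pvals)
  mask <- stats::p.adjust(pvals, method = "BH") <= q
  ord <- sort(pvals)
  ok <- ord <= seq_len(m) * q / m
  threshold <- if (any(ok)) max(ord[ok]) else 0
  list(mask = mask, threshold = threshold, q = q, n_tests = m,
       n_significant = sum(mask))
}
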