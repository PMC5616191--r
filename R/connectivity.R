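# Coherency-based measures separating zero-lag (volume-conducted) from
# lagged synchronization: coherence, imaginary coherence, coherence angle.

#' Coherency between two channels of a cross-spectral matrix
#'
#' Coherency is the cross-spectrum normalized by the square root of the two
#' power spectra: `C_ij(f) = S_ij(f) / sqrt(S_ii(f) S_jj(f))`. Its modulus
#' (coherence) measures phase-difference consistency; its imaginary part is
#' insensitive to instantaneous (zero-lag) mixing and so survives volume
#' conduction only when a true time lag exists; its argument is the phase
#' lag.
#'
#' @param csd A `cross_spectral_matrix` from [multitaper_csd()].
#' @param i,j Distinct channel indices.
#' @return A `coherency_result`: list with `freqs`, `coherency` (complex),
#'   `coherence` (in `[0, 1]`), `imag_coherence` (in `[-1, 1]`), `angle`
#'   (radians in `(-pi, pi]`), and `undefined` (logical; frequencies with
#'   nonpositive power, where the measure is flagged NA rather than 0).
#' @export
coherency <- function(csd, i, j) {
  stopifnot(inherits(csd, "cross_spectral_matrix"))
  if (i == j) stopf("channel indices must differ (self-coherency is trivially 1)")
  sii <- Re(csd$S[, i, i])
  sjj <- Re(csd$S[, j, j])
  undef <- !(sii > 0 & sjj > 0)
  denom <- sqrt(pmax(sii, 0) * pmax(sjj, 0))
  C <- csd$S[, i, j] / denom
  C[undef] <- NA_complex_
  coh <- Mod(C)
  # numerical guard: |C| can exceed 1 by rounding on degenerate inputs
  clip <- !is.na(coh) & coh > 1
  C[clip] <- C[clip] / coh[clip]
  coh <- pmin(coh, 1)
  structure(list(freqs = csd$freqs, coherency = C, coherence = coh,
                 imag_coherence = Im(C), angle = Arg(C), undefined = undef),
            class = "coherency_result")
}

#' Band-averaged zero-lag diagnostic
#'
#' Summaries used for the volume-conduction verdict: mean coherence, mean
#' imaginary coherence, and the angle of the band-averaged coherency. An
#' instantaneous common source yields high coherence with both the imaginary
#' part and the angle near zero; a genuinely lagged interaction pushes the
#' imaginary part away from zero.
#'
#' @param result A `coherency_result` from [coherency()].
#' @param band Frequency interval `c(lo, hi)` in Hz.
#' @return List with `mean_coherence`, `mean_imag`, `mean_angle` (radians).
#' @export
zero_lag_diagnostic <- function(result, band) {
  stopifnot(inherits(result, "coherency_result"))
  sel <- result$freqs >= band[1] & result$freqs <= band[2] &
    !result$undefined
  if (!any(sel)) stopf("band [%g, %g] Hz contains no defined frequencies",
                       band[1], band[2])
  list(mean_coherence = mean(result$coherence[sel]),
       mean_imag = mean(result$imag_coherence[sel]),
       mean_angle = Arg(mean(result$coherency[sel])))
}
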