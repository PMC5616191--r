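# Slepian taper computation and caching.

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the `k` most spectrally concentrated orthonormal tapers of length
#' `n` for a time-bandwidth product `nw`, using the classical symmetric
#' tridiagonal eigenproblem. These are the tapers underlying all multitaper
#' spectral estimates in this package.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (half-bandwidth in Hz times window
#'   duration in seconds). Must satisfy `0 < nw < n/2`.
#' @param k Number of tapers. Concentration degrades beyond `2*nw - 1`.
#' @return Numeric matrix `[n x k]`; columns are orthonormal
#'   (`crossprod(t) = I`), ordered from most to least concentrated.
#' @examples
#' t <- dpss_tapers(256, 4, 7)
#' max(abs(crossprod(t) - diag(7)))
#' @export
dpss_tapers <- function(n, nw, k) {
  n <- as.integer(n)
  k <- as.integer(k)
  stopifnot(n >= 2, k >= 1)
  if (k > n) stop("cannot compute more tapers than samples")
  if (nw <= 0 || nw >= n / 2) {
    stop(sprintf("time-bandwidth product nw = %g out of range (0, n/2)", nw))
  }
  key <- sprintf("n%d_nw%.10g_k%d", n, nw, k)
  got <- .dpss_cache[[key]]
  if (!is.null(got)) return(got)
  tp <- .dpss_tapers_cpp(n, nw, k)
  .dpss_cache[[key]] <- tp
  tp
}
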