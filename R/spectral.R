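# Multitaper spectral estimation with Slepian tapers: power spectra,
# Hermitian cross-spectral matrices, 1/f^2 "whitening", and a sliding-window
# spectrogram. Two smoothing modes are provided: a fixed half-bandwidth
# (single taper family, FFT onto a uniform grid) and a frequency-proportional
# half-bandwidth W(f) = c * f (one taper family per output frequency,
# evaluated by direct DFT at that frequency).

#' Spectral estimation configuration
#'
#' @param freqs Output frequency grid in Hz, or `NULL` for the full FFT grid
#'   from 0 to the Nyquist frequency (fixed-bandwidth mode only).
#' @param n_tapers Number of Slepian tapers (default 7).
#' @param smoothing_mode `"proportional"`: half-bandwidth `smoothing_param *
#'   f` at each output frequency `f`; `"fixed_bandwidth"`: a single
#'   half-bandwidth of `smoothing_param` Hz.
#' @param smoothing_param Dimensionless factor (proportional mode, default
#'   0.8) or half-bandwidth in Hz (fixed mode).
#' @return A `spectral_config` object.
#' @export
spectral_config <- function(freqs = seq(1, 20, by = 0.2), n_tapers = 7,
                            smoothing_mode = c("proportional",
                                               "fixed_bandwidth"),
                            smoothing_param = 0.8) {
  smoothing_mode <- match.arg(smoothing_mode)
  if (!is.null(freqs)) {
    if (any(freqs <= 0)) stopf("frequency grid must be positive")
    if (is.unsorted(freqs)) stopf("frequency grid must be increasing")
  }
  if (n_tapers < 1) stopf("n_tapers must be >= 1")
  if (smoothing_param <= 0) stopf("smoothing_param must be positive")
  structure(list(freqs = freqs, n_tapers = as.integer(n_tapers),
                 smoothing_mode = smoothing_mode,
                 smoothing_param = smoothing_param),
            class = "spectral_config")
}

# tapers for one output frequency under a given config; n = epoch length
.cfg_tapers <- function(cfg, f, n, fs) {
  w <- if (cfg$smoothing_mode == "proportional") cfg$smoothing_param * f else
    cfg$smoothing_param
  nw <- w * n / fs
  nw <- min(max(nw, 1), 0.45 * n)
  k <- min(cfg$n_tapers, n)
  if (cfg$smoothing_mode == "fixed_bandwidth" && k > max(1, floor(2 * nw - 1))) {
    stopf("n_tapers = %d inconsistent with half-bandwidth %g Hz (K must be <= 2NW-1 = %d)",
          cfg$n_tapers, w, max(1, floor(2 * nw - 1)))
  }
  dpss_tapers(n, nw, k)
}

.as_epoch_matrix <- function(epoch_matrix) {
  if (is.vector(epoch_matrix)) epoch_matrix <- matrix(epoch_matrix, nrow = 1)
  as.matrix(epoch_matrix)
}

# Tapered FFT cube for fixed-bandwidth mode: returns list(coefs [nfft x
# (n_epochs*k)], freqs). Columns are grouped by epoch (k tapers each).
.taper_fft <- function(epoch_matrix, fs, tapers) {
  n <- ncol(epoch_matrix)
  nfft <- next_pow2(n)
  k <- ncol(tapers)
  n_ep <- nrow(epoch_matrix)
  tx <- matrix(0, nfft, n_ep * k)
  for (e in seq_len(n_ep)) {
    tx[1:n, ((e - 1) * k + 1):(e * k)] <- tapers * epoch_matrix[e, ]
  }
  list(coefs = stats::mvfft(tx), freqs = (0:(nfft - 1)) * fs / nfft,
       nfft = nfft)
}

# Per-epoch multitaper power: returns list(freqs, power [n_epochs x n_freq])
.mt_power_per_epoch <- function(epoch_matrix, fs, cfg) {
  epoch_matrix <- .as_epoch_matrix(epoch_matrix)
  n <- ncol(epoch_matrix)
  if (n < 8) stopf("epochs of %d samples are too short for spectral estimation", n)
  n_ep <- nrow(epoch_matrix)

  if (cfg$smoothing_mode == "fixed_bandwidth") {
    tapers <- .cfg_tapers(cfg, NA, n, fs)
    k <- ncol(tapers)
    tf <- .taper_fft(epoch_matrix, fs, tapers)
    half <- which(tf$freqs <= fs / 2 + 1e-12)
    freqs_full <- tf$freqs[half]
    p2 <- Mod(tf$coefs[half, , drop = FALSE])^2 * 2 / fs
    # average tapers within each epoch
    pow_ep <- vapply(seq_len(n_ep), function(e) {
      rowMeans(p2[, ((e - 1) * k + 1):(e * k), drop = FALSE])
    }, numeric(length(half)))
    pow_ep[1, ] <- pow_ep[1, ] / 2                     # DC not doubled
    if (freqs_full[length(half)] == fs / 2) {
      pow_ep[length(half), ] <- pow_ep[length(half), ] / 2
    }
    if (is.null(cfg$freqs)) {
      list(freqs = freqs_full, power = t(pow_ep))
    } else {
      idx <- nearest_index(cfg$freqs, freqs_full)
      list(freqs = cfg$freqs, power = t(pow_ep[idx, , drop = FALSE]))
    }
  } else {
    if (is.null(cfg$freqs)) {
      stopf("proportional smoothing requires an explicit frequency grid")
    }
    freqs <- cfg$freqs
    tvec <- 0:(n - 1)
    pow <- vapply(freqs, function(f) {
      tapers <- .cfg_tapers(cfg, f, n, fs)
      e <- exp(-2i * pi * f * tvec / fs)
      M <- tapers * e                      # [n x k] complex
      X <- epoch_matrix %*% M              # [n_epochs x k]
      rowMeans(Mod(X)^2) * 2 / fs
    }, numeric(n_ep))
    if (n_ep == 1) pow <- matrix(pow, nrow = 1)
    list(freqs = freqs, power = pow)
  }
}

#' Multitaper power spectral density
#'
#' Tapers every epoch with Slepian sequences, Fourier-transforms, averages
#' squared moduli over tapers and epochs, and scales to a one-sided density
#' (the integral of a white-noise PSD over `[0, fs/2]` equals the signal
#' variance).
#'
#' @param epoch_matrix Numeric matrix `[n_epochs x n_samples]` (a vector is
#'   treated as a single epoch). All epochs must have equal length.
#' @param fs Sampling rate in Hz.
#' @param cfg A [spectral_config()].
#' @return A `spectral_estimate`: list with `freqs`, `power` (units^2/Hz),
#'   `n_epochs`, `fs`, `cfg`.
#' @export
multitaper_psd <- function(epoch_matrix, fs, cfg = spectral_config()) {
  epoch_matrix <- .as_epoch_matrix(epoch_matrix)
  pe <- .mt_power_per_epoch(epoch_matrix, fs, cfg)
  structure(list(freqs = pe$freqs, power = colMeans(pe$power),
                 n_epochs = nrow(epoch_matrix), fs = fs, cfg = cfg),
            class = "spectral_estimate")
}

#' Multitaper cross-spectral matrix
#'
#' Estimates the Hermitian cross-spectral density matrix
#' `S_ij(f) = E[X_i(f) conj(X_j(f))]` by averaging tapered Fourier
#' transforms over epochs and tapers. The diagonal equals [multitaper_psd()]
#' on the same data.
#'
#' @param epoch_tensor Numeric array `[n_epochs x n_channels x n_samples]`.
#' @param fs Sampling rate in Hz.
#' @param cfg A [spectral_config()]. With `freqs = NULL` (fixed-bandwidth
#'   mode) the full uniform FFT grid spanning `[0, fs/2]` is returned, as
#'   required by [wilson_factorize()].
#' @return A `cross_spectral_matrix`: list with `freqs`, `S` (complex array
#'   `[n_freq x n_ch x n_ch]`), `fs`, `n_epochs`, `nfft`, `cfg`.
#' @export
multitaper_csd <- function(epoch_tensor, fs, cfg = spectral_config()) {
  d <- dim(epoch_tensor)
  if (length(d) != 3) stopf("epoch_tensor must be [n_epochs x n_channels x n_samples]")
  n_ep <- d[1]; n_ch <- d[2]; n <- d[3]
  if (n_ch < 2) stopf("cross-spectra need at least 2 channels; use multitaper_psd")

  if (cfg$smoothing_mode == "fixed_bandwidth") {
    tapers <- .cfg_tapers(cfg, NA, n, fs)
    k <- ncol(tapers)
    tfs <- lapply(seq_len(n_ch), function(ch) {
      .taper_fft(epoch_tensor[, ch, , drop = TRUE], fs, tapers)
    })
    nfft <- tfs[[1]]$nfft
    half <- which(tfs[[1]]$freqs <= fs / 2 + 1e-12)
    freqs_full <- tfs[[1]]$freqs[half]
    S_full <- array(0i, c(length(half), n_ch, n_ch))
    for (i in seq_len(n_ch)) {
      for (j in i:n_ch) {
        cij <- rowMeans(tfs[[i]]$coefs[half, , drop = FALSE] *
                          Conj(tfs[[j]]$coefs[half, , drop = FALSE])) * 2 / fs
        S_full[, i, j] <- cij
        if (j > i) S_full[, j, i] <- Conj(cij)
      }
    }
    S_full[1, , ] <- S_full[1, , ] / 2
    if (freqs_full[length(half)] == fs / 2) {
      S_full[length(half), , ] <- S_full[length(half), , ] / 2
    }
    if (is.null(cfg$freqs)) {
      freqs <- freqs_full
      S <- S_full
    } else {
      idx <- nearest_index(cfg$freqs, freqs_full)
      freqs <- cfg$freqs
      S <- S_full[idx, , , drop = FALSE]
    }
  } else {
    if (is.null(cfg$freqs)) {
      stopf("proportional smoothing requires an explicit frequency grid")
    }
    freqs <- cfg$freqs
    nfft <- NA_integer_
    tvec <- 0:(n - 1)
    S <- array(0i, c(length(freqs), n_ch, n_ch))
    for (fi in seq_along(freqs)) {
      f <- freqs[fi]
      tapers <- .cfg_tapers(cfg, f, n, fs)
      e <- exp(-2i * pi * f * tvec / fs)
      M <- tapers * e
      X <- lapply(seq_len(n_ch), function(ch) {
        epoch_tensor[, ch, , drop = TRUE] %*% M   # [n_ep x k]
      })
      for (i in seq_len(n_ch)) {
        for (j in i:n_ch) {
          cij <- mean(X[[i]] * Conj(X[[j]])) * 2 / fs
          S[fi, i, j] <- cij
          if (j > i) S[fi, j, i] <- Conj(cij)
        }
      }
    }
  }
  structure(list(freqs = freqs, S = S, fs = fs, n_epochs = n_ep, nfft = nfft,
                 cfg = cfg), class = "cross_spectral_matrix")
}

#' Whiten a power spectrum by multiplying with frequency squared
#'
#' Compensates the 1/f^2 trend of LFP spectra so narrowband peaks stand out.
#'
#' @param est A `spectral_estimate` from [multitaper_psd()].
#' @return The estimate with `power(f) * f^2` and a `whitened` flag.
#' @export
whiten_psd <- function(est) {
  stopifnot(inherits(est, "spectral_estimate"))
  if (any(est$freqs <= 0)) stopf("whitening requires strictly positive frequencies")
  est$power <- est$power * est$freqs^2
  est$whitened <- TRUE
  est
}

#' Sliding-window multitaper spectrogram in decibel
#'
#' @param x Numeric vector (one channel) or an [lfp_recording()] (channel 1
#'   is used unless `channel` is given).
#' @param fs Sampling rate in Hz (ignored when `x` is a recording).
#' @param cfg A [spectral_config()]; the defaults for time-frequency display
#'   are a 2-20 Hz grid in 0.5 Hz steps, nine tapers, smoothing 0.2*f.
#' @param window Window length in seconds.
#' @param step Window step in seconds.
#' @param channel Channel index when `x` is a recording.
#' @param db_floor Lower clip for the decibel scale (default -120 dB).
#' @return List with `times` (window centers, s), `freqs` (Hz), and `db`
#'   (matrix `[n_freqs x n_windows]`, 10*log10 power, clipped at `db_floor`).
#' @export
spectrogram <- function(x, fs = NULL,
                        cfg = spectral_config(freqs = seq(2, 20, by = 0.5),
                                              n_tapers = 9,
                                              smoothing_param = 0.2),
                        window = 5, step = 1, channel = 1,
                        db_floor = -120) {
  if (inherits(x, "lfp_recording")) {
    fs <- x$fs
    x <- x$samples[channel, ]
  }
  if (is.null(fs)) stopf("fs required for plain numeric input")
  if (step <= 0) stopf("step must be positive")
  wn <- round(window * fs)
  if (wn > length(x)) stopf("window longer than the recording")
  sn <- max(1L, round(step * fs))
  starts <- seq(1L, length(x) - wn + 1L, by = sn)
  segs <- t(vapply(starts, function(s) x[s:(s + wn - 1)], numeric(wn)))
  pe <- .mt_power_per_epoch(segs, fs, cfg)
  db <- t(pmax(10 * log10(pmax(pe$power, 10^(db_floor / 10))), db_floor))
  list(times = (starts - 1 + wn / 2) / fs, freqs = pe$freqs, db = db)
}

#' Whitened spectral peak-to-flank ratio
#'
#' Ratio of power at the peak frequency to the mean power at flank
#' frequencies, the package's summary of how prominent a narrowband peak is.
#' Computed on whichever scale the estimate carries; pass a whitened
#' estimate (see [whiten_psd()]) for the whitened ratio.
#'
#' @param est A `spectral_estimate`.
#' @param peak_freq Peak frequency in Hz (default 8).
#' @param flank_freqs Flank frequencies in Hz (default `c(5, 12)`, outside
#'   the 6-10 Hz theta band).
#' @return Scalar ratio.
#' @export
peak_flank_ratio <- function(est, peak_freq = 8, flank_freqs = c(5, 12)) {
  stopifnot(inherits(est, "spectral_estimate"))
  pk <- est$power[nearest_index(peak_freq, est$freqs)]
  fl <- mean(est$power[nearest_index(flank_freqs, est$freqs)])
  pk / fl
}
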