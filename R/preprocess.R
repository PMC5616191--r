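# Preprocessing: container for continuous recordings, downsampling,
# band-pass + notch filtering, variance-based artifact flagging, epoch
# extraction from trial tables, and the two rereferencing derivations.

#' Multichannel continuous recording
#'
#' @param samples Numeric matrix `[n_channels x n_samples]`.
#' @param fs Sampling rate in Hz.
#' @param channel_shank_map Integer shank/tetrode id per channel.
#' @param channel_regions Optional character region label per channel.
#' @return An `lfp_recording` object.
#' @export
lfp_recording <- function(samples, fs, channel_shank_map,
                          channel_regions = NULL) {
  samples <- as.matrix(samples)
  if (fs <= 0) stopf("sampling rate must be positive")
  if (length(channel_shank_map) != nrow(samples)) {
    stopf("channel_shank_map must map every channel to exactly one shank")
  }
  if (is.null(channel_regions)) {
    channel_regions <- rep("unknown", nrow(samples))
  }
  structure(list(samples = samples, fs = fs,
                 channel_shank_map = as.integer(channel_shank_map),
                 channel_regions = as.character(channel_regions)),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  cat("  shanks:", paste(unique(x$channel_shank_map), collapse = ", "), "\n")
  invisible(x)
}

#' Integer-factor downsampling with anti-alias filtering
#'
#' Low-pass filters each channel below the target Nyquist frequency
#' (zero-phase Butterworth, cutoff at 0.4 times the target rate) and then
#' decimates.
#'
#' @param rec An [lfp_recording()].
#' @param target_fs Target sampling rate; `rec$fs` must be an integer
#'   multiple of it.
#' @return The downsampled recording with `floor(n / factor)` samples.
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "lfp_recording"))
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    valid <- rec$fs / seq_len(32)
    valid <- valid[abs(valid - round(valid) * 0) >= 0 & valid == round(valid)]
    stopf(paste0("fs = %g is not an integer multiple of target_fs = %g; ",
                 "nearest valid target rates: %s"),
          rec$fs, target_fs,
          paste(utils::head(valid[order(abs(valid - target_fs))], 3),
                collapse = ", "))
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  bf <- signal::butter(8, 0.4 * target_fs / (rec$fs / 2), type = "low")
  n_out <- floor(ncol(rec$samples) / factor)
  idx <- seq(1L, n_out * factor, by = factor)
  out <- t(apply(rec$samples, 1, function(ch) {
    signal::filtfilt(bf, ch)[idx]
  }))
  lfp_recording(out, target_fs, rec$channel_shank_map, rec$channel_regions)
}

#' Zero-phase band-pass and power-line notch filtering
#'
#' Applies a forward-backward high-pass/low-pass cascade for the passband and
#' second-order Butterworth band-stop notches at every integer multiple of
#' `notch_base` up to the Nyquist frequency.
#'
#' @param rec An [lfp_recording()].
#' @param band Passband `[low, high]` in Hz (default `c(0.1, 250)`).
#' @param notch_base Power-line fundamental in Hz (default 50); set to `NULL`
#'   to skip notching.
#' @param notch_halfwidth Half-width of each notch in Hz (default 1).
#' @return The filtered recording.
#' @export
bandpass_notch <- function(rec, band = c(0.1, 250), notch_base = 50,
                           notch_halfwidth = 1) {
  stopifnot(inherits(rec, "lfp_recording"))
  nyq <- rec$fs / 2
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2]) {
    stopf("passband [%g, %g] Hz must lie inside (0, %g) Hz", band[1], band[2],
          nyq)
  }
  hp <- signal::butter(1, band[1] / nyq, type = "high")
  lp <- signal::butter(4, band[2] / nyq, type = "low")
  notches <- list()
  if (!is.null(notch_base)) {
    f0s <- seq(notch_base, nyq - notch_halfwidth - 1e-9, by = notch_base)
    notches <- lapply(f0s, function(f0) {
      signal::butter(2, c(f0 - notch_halfwidth, f0 + notch_halfwidth) / nyq,
                     type = "stop")
    })
  }
  out <- t(apply(rec$samples, 1, function(ch) {
    y <- signal::filtfilt(hp, ch)
    y <- signal::filtfilt(lp, y)
    for (nf in notches) y <- signal::filtfilt(nf, y)
    y
  }))
  lfp_recording(out, rec$fs, rec$channel_shank_map, rec$channel_regions)
}

#' Flag artifact epochs by cross-epoch variance z-scores
#'
#' For every epoch and channel the signal variance is computed; variances are
#' z-scored across epochs within each channel, and an epoch is flagged when
#' any channel's absolute z-score exceeds `z_thresh`. The data are not
#' modified.
#'
#' @param rec An [lfp_recording()].
#' @param epochs Epoch set (see [extract_epochs()]).
#' @param z_thresh Flagging threshold (default 4).
#' @return Data frame with one row per epoch: `label`, `start`, `end`,
#'   `max_abs_z`, `flagged`.
#' @export
detect_artifacts <- function(rec, epochs, z_thresh = 4) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (nrow(epochs) == 0) stopf("empty epoch list")
  if (nrow(epochs) < 2) stopf("need at least 2 epochs to z-score variances")
  v <- vapply(seq_len(nrow(epochs)), function(i) {
    idx <- (epochs$start[i] + 1):epochs$end[i]
    apply(rec$samples[, idx, drop = FALSE], 1, stats::var)
  }, numeric(nrow(rec$samples)))
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  v <- t(v)                      # [n_epochs x n_channels]
  z <- scale(v)  # per-channel z across epochs
  z[is.nan(z)] <- 0
  max_abs_z <- apply(abs(z), 1, max)
  data.frame(label = epochs$label, start = epochs$start, end = epochs$end,
             max_abs_z = max_abs_z, flagged = max_abs_z > z_thresh,
             stringsAsFactors = FALSE)
}

#' Build run/baseline epochs from a trial table
#'
#' Each included trial yields one run epoch covering the `epoch_len` seconds
#' preceding entry into the stop area, and one baseline epoch placed in the
#' latest admissible window of the preceding intertrial interval. Trials with
#' duration (stop-area entry minus trial start) at or below `min_duration`
#' or marked incorrect are excluded; when the intertrial interval cannot
#' hold a full baseline epoch the run epoch is kept and the baseline dropped
#' with a warning (paired analyses later match run/baseline counts).
#'
#' @param trials Data frame with columns `trial_id`, `trial_start_s`,
#'   `stop_entry_s`, `intertrial_start_s`, `intertrial_end_s`, `correct`.
#' @param epoch_len Epoch length in seconds (default 5).
#' @param fs Sampling rate in Hz used to convert to sample indices.
#' @param min_duration Minimum trial duration in seconds (default 7; trials
#'   must be strictly longer).
#' @return An epoch set: data frame with `label` (`"run"`/`"baseline"`),
#'   `start`, `end` in 0-based half-open sample indices, every epoch exactly
#'   `round(epoch_len * fs)` samples long.
#' @export
extract_epochs <- function(trials, epoch_len = 5, fs, min_duration = 7) {
  need <- c("trial_id", "trial_start_s", "stop_entry_s", "intertrial_start_s",
            "intertrial_end_s", "correct")
  if (!all(need %in% names(trials))) {
    stopf("trial table must have columns: %s", paste(need, collapse = ", "))
  }
  ep_n <- round(epoch_len * fs)
  rows <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    if (!tr$correct) next
    if ((tr$stop_entry_s - tr$trial_start_s) <= min_duration) next
    run_end <- round(tr$stop_entry_s * fs)
    run_start <- run_end - ep_n
    if (run_start < 0) {
      warning(sprintf("trial %s: run epoch would start before the recording; dropped",
                      tr$trial_id))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      label = "run", start = run_start, end = run_end,
      stringsAsFactors = FALSE)
    bl_end_s <- min(tr$intertrial_end_s, tr$trial_start_s)
    bl_end <- round(bl_end_s * fs)
    bl_start <- bl_end - ep_n
    if (bl_start < round(tr$intertrial_start_s * fs) || bl_start < 0) {
      warning(sprintf("trial %s: intertrial interval shorter than %g s; baseline dropped",
                      tr$trial_id, epoch_len))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      label = "baseline", start = bl_start, end = bl_end,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), start = integer(), end = integer())
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  class(out) <- c("epoch_set", "data.frame")
  attr(out, "epoch_len") <- epoch_len
  attr(out, "fs") <- fs
  out
}

#' Bipolar rereferencing against another shank
#'
#' Subtracts the mean signal of the reference shank from every channel of the
#' target shank; other channels are dropped. Signals shared identically
#' across both shanks (e.g. volume-conducted sources with equal gains) cancel
#' exactly.
#'
#' @param rec An [lfp_recording()].
#' @param target_shank,reference_shank Distinct shank ids present in the
#'   recording.
#' @return An [lfp_recording()] containing the rereferenced target channels.
#' @export
rereference_bipolar <- function(rec, target_shank, reference_shank) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (target_shank == reference_shank) {
    stopf("target and reference shank must differ")
  }
  ti <- which(rec$channel_shank_map == target_shank)
  ri <- which(rec$channel_shank_map == reference_shank)
  if (!length(ti)) stopf("target shank %s not found", target_shank)
  if (!length(ri)) stopf("reference shank %s not found", reference_shank)
  ref <- colMeans(rec$samples[ri, , drop = FALSE])
  out <- sweep(rec$samples[ti, , drop = FALSE], 2, ref, "-")
  lfp_recording(out, rec$fs, rec$channel_shank_map[ti],
                rec$channel_regions[ti])
}

#' Common-average rereferencing across shanks
#'
#' Computes one mean signal per shank, averages those across shanks into a
#' single common reference, and subtracts it from every channel.
#'
#' @param rec An [lfp_recording()] with at least two shanks.
#' @return The rereferenced recording (same channels).
#' @export
rereference_car <- function(rec) {
  stopifnot(inherits(rec, "lfp_recording"))
  shanks <- unique(rec$channel_shank_map)
  if (length(shanks) < 2) stopf("common-average reference needs >= 2 shanks")
  per_shank <- vapply(shanks, function(s) {
    colMeans(rec$samples[rec$channel_shank_map == s, , drop = FALSE])
  }, numeric(ncol(rec$samples)))
  ref <- rowMeans(per_shank)
  out <- sweep(rec$samples, 2, ref, "-")
  lfp_recording(out, rec$fs, rec$channel_shank_map, rec$channel_regions)
}
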