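# File interchange: flat binary recordings with a JSON sidecar, spike and
# epoch tables as CSV, configuration as YAML.

#' Write a recording as flat binary with a JSON sidecar
#'
#' Samples are stored as little-endian float32 in channel-major frames (all
#' channels of sample 1, then all channels of sample 2, ...), alongside a
#' JSON sidecar holding the sampling rate, channel maps, and provenance.
#'
#' @param rec An [lfp_recording()].
#' @param bin_path Output `.dat` path.
#' @param json_path Sidecar path; default `bin_path` with `.json` appended.
#' @param scenario,seed Optional provenance fields stored in the sidecar.
#' @return Invisibly, the sidecar list.
#' @export
write_recording <- function(rec, bin_path, json_path = paste0(bin_path, ".json"),
                            scenario = NULL, seed = NULL) {
  stopifnot(inherits(rec, "lfp_recording"))
  con <- file(bin_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$samples), con, size = 4, endian = "little")
  side <- list(fs_hz = rec$fs, n_channels = nrow(rec$samples),
               n_samples = ncol(rec$samples),
               channel_shank_map = rec$channel_shank_map,
               channel_regions = rec$channel_regions,
               scenario = scenario, seed = seed)
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))], json_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a flat binary recording and its JSON sidecar
#'
#' @param bin_path Binary file written by [write_recording()].
#' @param json_path Sidecar path; default `bin_path` with `.json` appended.
#' @return An [lfp_recording()].
#' @export
read_recording <- function(bin_path, json_path = paste0(bin_path, ".json")) {
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  n_ch <- side$n_channels
  con <- file(bin_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, numeric(), n = side$n_channels * side$n_samples,
                 size = 4, endian = "little")
  lfp_recording(matrix(raw, nrow = n_ch), side$fs_hz,
                side$channel_shank_map,
                side$channel_regions %||% NULL)
}

#' Write spike times as CSV (`unit_id,time_s`)
#' @param spikes Named list of spike-time vectors (seconds).
#' @param path Output path.
#' @export
write_spikes <- function(spikes, path) {
  df <- do.call(rbind, lapply(names(spikes), function(u) {
    if (length(spikes[[u]]) == 0) return(NULL)
    data.frame(unit_id = u, time_s = spikes[[u]])
  }))
  if (is.null(df)) df <- data.frame(unit_id = character(), time_s = numeric())
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read spike times from CSV (`unit_id,time_s`)
#' @param path CSV path.
#' @return Named list of sorted spike-time vectors.
#' @export
read_spikes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df$time_s, df$unit_id), sort)
}

#' Write an epoch set as CSV (`label,start_s,end_s`)
#' @param epochs Epoch set with sample indices (see [extract_epochs()]).
#' @param path Output path.
#' @param fs Sampling rate used to convert to seconds; defaults to the
#'   epoch set's own.
#' @export
write_epoch_set <- function(epochs, path, fs = attr(epochs, "fs")) {
  if (is.null(fs)) stopf("sampling rate unknown; pass fs")
  utils::write.csv(data.frame(label = epochs$label,
                              start_s = epochs$start / fs,
                              end_s = epochs$end / fs),
                   path, row.names = FALSE)
}

#' Read an epoch set from CSV (`label,start_s,end_s`)
#' @param path CSV path.
#' @param fs Sampling rate in Hz for conversion to sample indices.
#' @return An epoch set data frame (`label`, `start`, `end` in samples).
#' @export
read_epoch_set <- function(path, fs) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(label = df$label, start = round(df$start_s * fs),
                    end = round(df$end_s * fs), stringsAsFactors = FALSE)
  class(out) <- c("epoch_set", "data.frame")
  attr(out, "fs") <- fs
  out
}

#' Read a trial table CSV
#'
#' Expected columns: `trial_id`, `trial_start_s`, `stop_entry_s`,
#' `intertrial_start_s`, `intertrial_end_s`, `correct`.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_trials <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Write / read an analysis configuration as YAML
#' @param config A plain list.
#' @param path YAML path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(rapply(config, unclass, how = "replace"), path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) yaml::read_yaml(path)
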