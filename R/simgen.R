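# Synthetic multichannel LFP and spike-train generator with known ground
# truth: narrowband sources spread instantaneously across channels (volume
# conduction), optional lagged directed coupling between channel groups, and
# units phase-modulated by a source's oscillation.

#' Specify a signal source
#'
#' A source is either a stochastic narrowband oscillator (an AR(2) process
#' with a complex pole pair at the requested frequency) or broadband white
#' noise. Amplitudes are the stationary standard deviation of the series and
#' may differ between "run" and "baseline" epochs of a session.
#'
#' @param center_freq Peak frequency in Hz.
#' @param bandwidth Spectral full width in Hz controlling the pole modulus
#'   (`r = exp(-pi * bandwidth / fs)`).
#' @param amplitude_run,amplitude_baseline Stationary standard deviation of
#'   the series in each condition (signal units).
#' @param kind `"narrowband_ar2"` or `"broadband_noise"`.
#' @return A `source_spec` object.
#' @export
source_spec <- function(center_freq, bandwidth, amplitude_run,
                        amplitude_baseline = amplitude_run,
                        kind = c("narrowband_ar2", "broadband_noise")) {
  kind <- match.arg(kind)
  if (center_freq <= 0) stopf("center_freq must be positive")
  if (bandwidth <= 0) stopf("bandwidth must be positive")
  if (amplitude_run < 0 || amplitude_baseline < 0) {
    stopf("amplitudes must be nonnegative")
  }
  structure(list(center_freq = center_freq, bandwidth = bandwidth,
                 amplitude_run = amplitude_run,
                 amplitude_baseline = amplitude_baseline, kind = kind),
            class = "source_spec")
}

#' Specify instantaneous source-to-channel mixing
#'
#' Models passive volume conduction: every channel receives a zero-lag scaled
#' copy of each source.
#'
#' @param gains Numeric matrix `[n_channels x n_sources]` of dimensionless
#'   gains.
#' @return A `mixing_map` object.
#' @export
mixing_map <- function(gains) {
  gains <- as.matrix(gains)
  if (!all(is.finite(gains))) stopf("mixing gains must be finite")
  structure(list(gains = gains), class = "mixing_map")
}

#' Specify a lagged vector-autoregressive coupling
#'
#' Ground truth for directed interactions: a stationary VAR whose coefficient
#' `var_coeffs[k, i, j]` multiplies channel `j` at lag `k * lag_step` samples
#' when predicting channel `i`.
#'
#' @param var_coeffs Array `[order x n x n]` of AR coefficients.
#' @param noise_cov Symmetric positive-definite innovation covariance.
#' @param lag_step Lag unit in samples (default 1).
#' @return A `coupling_spec` object.
#' @export
coupling_spec <- function(var_coeffs, noise_cov, lag_step = 1L) {
  if (length(dim(var_coeffs)) == 2) {
    var_coeffs <- array(var_coeffs, c(1, dim(var_coeffs)))
  }
  d <- dim(var_coeffs)
  if (length(d) != 3 || d[2] != d[3]) {
    stopf("var_coeffs must be an [order x n x n] array")
  }
  noise_cov <- as.matrix(noise_cov)
  if (nrow(noise_cov) != d[2] || !isSymmetric(noise_cov, tol = 1e-10)) {
    stopf("noise_cov must be a symmetric [n x n] matrix")
  }
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stopf("noise_cov must be positive definite")
  spec <- structure(list(var_coeffs = var_coeffs, noise_cov = noise_cov,
                         lag_step = as.integer(lag_step)),
                    class = "coupling_spec")
  rho <- var_spectral_radius(spec)
  if (rho >= 1) {
    stopf("unstable VAR coefficients: companion spectral radius %.4f >= 1", rho)
  }
  spec
}

#' Companion-matrix spectral radius of a VAR coupling
#' @param coupling A [coupling_spec()].
#' @return The spectral radius; stationarity requires a value below 1.
#' @export
var_spectral_radius <- function(coupling) {
  A <- coupling$var_coeffs
  p <- dim(A)[2]
  maxlag <- dim(A)[1] * coupling$lag_step
  comp <- matrix(0, p * maxlag, p * maxlag)
  for (k in seq_len(dim(A)[1])) {
    lag <- k * coupling$lag_step
    comp[1:p, ((lag - 1) * p + 1):(lag * p)] <- A[k, , ]
  }
  if (maxlag > 1) {
    comp[(p + 1):(p * maxlag), 1:(p * (maxlag - 1))] <-
      diag(p * (maxlag - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Specify a phase-modulated unit
#'
#' Spikes are an inhomogeneous Poisson process with intensity
#' `base_rate * exp(kappa * cos(phase - pref_phase)) / I0(kappa)`, so the
#' marginal mean rate equals `base_rate` and the spike-phase distribution is
#' von Mises with concentration `kappa` and mean `pref_phase`.
#'
#' @param base_rate Mean firing rate in spikes/s.
#' @param kappa von Mises concentration (0 = unmodulated).
#' @param pref_phase Preferred phase in degrees, in (-180, 180].
#' @param source_index Which session source's phase modulates the unit.
#' @return A `spike_mod_spec` object.
#' @export
spike_mod_spec <- function(base_rate, kappa, pref_phase = 0,
                           source_index = 1L) {
  if (base_rate < 0) stopf("base_rate must be nonnegative")
  if (kappa < 0) stopf("kappa must be nonnegative")
  structure(list(base_rate = base_rate, kappa = kappa,
                 pref_phase = wrap_deg(pref_phase),
                 source_index = as.integer(source_index)),
            class = "spike_mod_spec")
}

# ---- generators (consume the current RNG stream) ----

.gen_source <- function(spec, n, fs, amplitude) {
  if (spec$kind == "broadband_noise") {
    return(amplitude * stats::rnorm(n))
  }
  f0 <- spec$center_freq
  bw <- spec$bandwidth
  if (fs <= 2 * (f0 + bw)) {
    stopf("sampling rate %g Hz too low for a %g Hz source (need fs > %g)",
          fs, f0, 2 * (f0 + bw))
  }
  r <- exp(-pi * bw / fs)
  w <- 2 * pi * f0 / fs
  a1 <- 2 * r * cos(w)
  a2 <- -r^2
  # innovation sd giving stationary sd = amplitude (Yule-Walker closed form)
  g <- (1 + a2) * ((1 - a2)^2 - a1^2) / (1 - a2)
  sd_e <- amplitude * sqrt(g)
  burn <- ceiling(8 * fs / (pi * bw))
  e <- stats::rnorm(n + burn, sd = sd_e)
  x <- stats::filter(e, c(a1, a2), method = "recursive")
  as.numeric(x[(burn + 1):(burn + n)])
}

.gen_var <- function(coupling, n, burn = NULL) {
  A <- coupling$var_coeffs
  order <- dim(A)[1]
  p <- dim(A)[2]
  if (is.null(burn)) burn <- 10L * order * coupling$lag_step + 100L
  total <- n + burn
  U <- chol(coupling$noise_cov)
  innov <- matrix(stats::rnorm(total * p), total, p) %*% U
  .simulate_var_cpp(as.numeric(A), order, p, innov, coupling$lag_step, burn)
}

.gen_spikes <- function(phase_series, mod, fs) {
  if (mod$base_rate == 0) return(numeric(0))
  n <- length(phase_series)
  duration <- n / fs
  # envelope rate for Lewis-Shedler thinning
  lam_max <- mod$base_rate / besselI(mod$kappa, 0, expon.scaled = TRUE)
  n_cand <- stats::rpois(1, lam_max * duration)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, 0, duration))
  rad <- phase_series * pi / 180
  tgrid <- (seq_len(n) - 1) / fs
  cphi <- stats::approx(tgrid, cos(rad), xout = cand, rule = 2)$y
  sphi <- stats::approx(tgrid, sin(rad), xout = cand, rule = 2)$y
  theta <- mod$pref_phase * pi / 180
  # lambda(t)/lambda_max = exp(kappa * (cos(phi - theta) - 1))
  cosd <- cphi * cos(theta) + sphi * sin(theta)
  keep <- stats::runif(n_cand) < exp(mod$kappa * (cosd - 1))
  cand[keep]
}

# ---- exported seeded wrappers ----

#' Simulate a stochastic narrowband oscillation
#'
#' Generates a zero-mean series whose spectral peak sits at the source's
#' center frequency, as an AR(2) process with pole modulus set by the
#' bandwidth, scaled so the stationary standard deviation equals
#' `amplitude_run`.
#'
#' @param spec A [source_spec()].
#' @param duration Length in seconds.
#' @param fs Sampling rate in Hz; must exceed twice `center_freq + bandwidth`.
#' @param seed Integer seed; identical seeds give identical series.
#' @return Numeric vector of `round(duration * fs)` samples.
#' @export
simulate_theta_source <- function(spec, duration, fs, seed) {
  stopifnot(inherits(spec, "source_spec"), duration > 0)
  n <- round(duration * fs)
  with_seed(seed, .gen_source(spec, n, fs, spec$amplitude_run))
}

#' Simulate a vector autoregression
#'
#' @param coupling A [coupling_spec()] (stationarity is enforced at
#'   construction).
#' @param n_samples Number of samples to return after discarding a burn-in of
#'   at least ten times the model order.
#' @param fs Sampling rate in Hz (metadata only).
#' @param seed Integer seed.
#' @return Numeric matrix `[n_samples x n_channels]`.
#' @export
simulate_var <- function(coupling, n_samples, fs, seed) {
  stopifnot(inherits(coupling, "coupling_spec"))
  with_seed(seed, .gen_var(coupling, n_samples))
}

#' Simulate a phase-modulated spike train
#'
#' Inhomogeneous Poisson spikes with a von Mises intensity profile on the
#' oscillation phase, generated by Lewis-Shedler thinning.
#'
#' @param phase_series Instantaneous phase in degrees, one value per sample
#'   (0 degrees at the oscillation peak).
#' @param mod A [spike_mod_spec()].
#' @param fs Sampling rate of `phase_series` in Hz.
#' @param seed Integer seed.
#' @return Sorted spike times in seconds, within `[0, length(phase)/fs)`.
#' @export
simulate_spike_train <- function(phase_series, mod, fs, seed) {
  stopifnot(inherits(mod, "spike_mod_spec"))
  with_seed(seed, .gen_spikes(phase_series, mod, fs))
}

#' Assemble a session configuration
#'
#' @param scenario `"volume_conduction"` (instantaneous mixing only),
#'   `"lagged_coupling"` (VAR-coupled channel groups), or `"mixed"`.
#' @param sources List of [source_spec()] objects.
#' @param mixing A [mixing_map()] with one row per channel, one column per
#'   source.
#' @param coupling Optional [coupling_spec()]; forbidden under
#'   `"volume_conduction"`, required otherwise.
#' @param coupling_gains Matrix `[n_channels x n_nodes]` mapping VAR node
#'   series onto channels.
#' @param coupling_delays Optional integer matrix of per-channel sample delays
#'   applied to node series before mixing (models traveling phase gradients).
#' @param spike_specs List of [spike_mod_spec()] objects (may be empty).
#' @param n_trials Number of trials; each contributes one baseline and one
#'   run epoch.
#' @param epoch_len Epoch length in seconds (default 5).
#' @param gap_len Inter-epoch gap in seconds (default 2).
#' @param fs Sampling rate in Hz (default 1250).
#' @param noise_sd Independent white local noise standard deviation, scalar or
#'   per channel.
#' @param channel_shank_map Integer shank id per channel.
#' @param channel_regions Character region label per channel (e.g.
#'   `"striatum"`, `"cortex"`).
#' @param seed Integer seed.
#' @return A `session_config` list.
#' @export
session_config <- function(scenario = c("volume_conduction", "lagged_coupling",
                                        "mixed"),
                           sources, mixing, coupling = NULL,
                           coupling_gains = NULL, coupling_delays = NULL,
                           spike_specs = list(), n_trials = 12,
                           epoch_len = 5, gap_len = 2, fs = 1250,
                           noise_sd = 0.05, channel_shank_map,
                           channel_regions = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  n_ch <- nrow(mixing$gains)
  if (length(sources) != ncol(mixing$gains)) {
    stopf("mixing map has %d source columns but %d sources given",
          ncol(mixing$gains), length(sources))
  }
  if (scenario == "volume_conduction" && !is.null(coupling)) {
    stopf("a coupling_spec is not allowed under the volume_conduction scenario")
  }
  if (scenario != "volume_conduction" && is.null(coupling)) {
    stopf("scenario '%s' requires a coupling_spec", scenario)
  }
  if (!is.null(coupling)) {
    if (is.null(coupling_gains)) stopf("coupling_gains required with coupling")
    coupling_gains <- as.matrix(coupling_gains)
    if (nrow(coupling_gains) != n_ch ||
        ncol(coupling_gains) != dim(coupling$var_coeffs)[2]) {
      stopf("coupling_gains must be [n_channels x n_nodes]")
    }
    if (is.null(coupling_delays)) {
      coupling_delays <- matrix(0L, n_ch, ncol(coupling_gains))
    }
  }
  if (length(channel_shank_map) != n_ch) {
    stopf("channel_shank_map must have one entry per channel")
  }
  if (is.null(channel_regions)) channel_regions <- rep("striatum", n_ch)
  structure(list(scenario = scenario, sources = sources, mixing = mixing,
                 coupling = coupling, coupling_gains = coupling_gains,
                 coupling_delays = coupling_delays, spike_specs = spike_specs,
                 n_trials = as.integer(n_trials), epoch_len = epoch_len,
                 gap_len = gap_len, fs = fs, noise_sd = noise_sd,
                 channel_shank_map = as.integer(channel_shank_map),
                 channel_regions = channel_regions, seed = as.integer(seed)),
            class = "session_config")
}

#' Simulate a full recording session
#'
#' Builds a continuous multichannel recording laid out as alternating
#' baseline and run epochs separated by gaps. Channels are the instantaneous
#' mixture of the sources (amplitude-stepped per epoch condition) plus
#' independent white local noise, plus any lagged VAR contribution. Units are
#' phase-modulated by their assigned source. The ground truth (all specs, the
#' seed, and the raw source series) is stored alongside the data.
#'
#' @param config A [session_config()].
#' @return A `synthetic_dataset` list with elements `recording`
#'   ([lfp_recording()]), `spikes` (named list of spike-time vectors),
#'   `epochs` (an epoch set; see [extract_epochs()]), and `truth`.
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  fs <- config$fs
  ep_n <- round(config$epoch_len * fs)
  gap_n <- round(config$gap_len * fs)
  n_ch <- nrow(config$mixing$gains)
  n_src <- length(config$sources)

  # session layout: gap, then per trial [baseline, gap, run, gap]
  starts_baseline <- integer(config$n_trials)
  starts_run <- integer(config$n_trials)
  pos <- gap_n
  for (i in seq_len(config$n_trials)) {
    starts_baseline[i] <- pos
    pos <- pos + ep_n + gap_n
    starts_run[i] <- pos
    pos <- pos + ep_n + gap_n
  }
  n <- pos

  epochs <- data.frame(
    label = rep(c("baseline", "run"), each = config$n_trials),
    start = c(starts_baseline, starts_run),
    end = c(starts_baseline, starts_run) + ep_n,
    stringsAsFactors = FALSE
  )
  epochs <- epochs[order(epochs$start), ]
  rownames(epochs) <- NULL
  class(epochs) <- c("epoch_set", "data.frame")
  attr(epochs, "epoch_len") <- config$epoch_len
  attr(epochs, "fs") <- fs

  run_mask <- logical(n)
  for (s in starts_run) run_mask[(s + 1):(s + ep_n)] <- TRUE

  out <- with_seed(config$seed, {
    src_unit <- matrix(0, n, n_src)
    src_env <- matrix(0, n, n_src)
    for (k in seq_len(n_src)) {
      sp <- config$sources[[k]]
      src_unit[, k] <- .gen_source(sp, n, fs, 1)
      amp <- ifelse(run_mask, sp$amplitude_run, sp$amplitude_baseline)
      src_env[, k] <- src_unit[, k] * amp
    }
    x <- config$mixing$gains %*% t(src_env)  # [n_ch x n]

    nodes <- NULL
    if (!is.null(config$coupling)) {
      nodes <- .gen_var(config$coupling, n)
      for (ch in seq_len(n_ch)) {
        for (m in seq_len(ncol(nodes))) {
          g <- config$coupling_gains[ch, m]
          if (g == 0) next
          d <- config$coupling_delays[ch, m]
          v <- nodes[, m]
          if (d > 0) v <- c(rep(0, d), v[seq_len(n - d)])
          x[ch, ] <- x[ch, ] + g * v
        }
      }
    }

    sd_noise <- rep(config$noise_sd, length.out = n_ch)
    for (ch in seq_len(n_ch)) {
      x[ch, ] <- x[ch, ] + stats::rnorm(n, sd = sd_noise[ch])
    }

    spikes <- list()
    if (length(config$spike_specs) > 0) {
      for (u in seq_along(config$spike_specs)) {
        mod <- config$spike_specs[[u]]
        phase <- Arg(analytic_signal(src_unit[, mod$source_index])) * 180 / pi
        spikes[[sprintf("unit%02d", u)]] <- .gen_spikes(phase, mod, fs)
      }
    }
    list(x = x, spikes = spikes, src_unit = src_unit, nodes = nodes)
  })

  rec <- lfp_recording(out$x, fs, config$channel_shank_map,
                       config$channel_regions)
  structure(list(
    recording = rec,
    spikes = out$spikes,
    epochs = epochs,
    truth = list(scenario = config$scenario, config = config,
                 seed = config$seed, source_series = out$src_unit,
                 node_series = out$nodes)
  ), class = "synthetic_dataset")
}
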