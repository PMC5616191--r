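test_that("narrowband source peaks at its center frequency with unit sd", {
  sp <- source_spec(8, 1, 1)
  x <- simulate_theta_source(sp, 100, 1250, 7)
  expect_equal(length(x), 125000)
  expect_equal(sd(x), 1, tolerance = 0.05)
  expect_equal(mean(x), 0, tolerance = 0.05)
  est <- multitaper_psd(matrix(x, nrow = 20, byrow = TRUE), 1250,
                        spectral_config(freqs = seq(1, 20, 0.2),
                                        smoothing_mode = "fixed_bandwidth",
                                        smoothing_param = 1))
  expect_lte(abs(est$freqs[which.max(est$power)] - 8), 0.2)
})

test_that("source generation honors amplitude, seed, and aliasing guards", {
  sp0 <- source_spec(8, 1, 0)
  expect_true(all(simulate_theta_source(sp0, 1, 1250, 1) == 0))
  sp <- source_spec(8, 1, 1)
  expect_identical(simulate_theta_source(sp, 1, 1250, 3),
                   simulate_theta_source(sp, 1, 1250, 3))
  expect_false(identical(simulate_theta_source(sp, 1, 1250, 3),
                         simulate_theta_source(sp, 1, 1250, 4)))
  expect_error(simulate_theta_source(source_spec(8, 1, 1), 1, 10, 1),
               "sampling rate")
  expect_error(source_spec(-1, 1, 1))
  expect_error(source_spec(8, 1, -2))
})

test_that("VAR simulation matches Yule-Walker closed forms", {
  # uncoupled white noise: sample covariance near identity
  cp0 <- coupling_spec(array(0, c(1, 2, 2)), diag(2))
  x0 <- simulate_var(cp0, 20000, 100, 5)
  expect_lt(max(abs(cov(x0) - diag(2))), 4 / sqrt(20000))

  # univariate AR(1), phi = 0.9: var = 1/(1 - 0.81), lag-1 autocorr = 0.9
  cp1 <- coupling_spec(array(0.9, c(1, 1, 1)), matrix(1))
  x1 <- simulate_var(cp1, 200000, 100, 6)[, 1]
  expect_equal(var(x1), 1 / (1 - 0.81), tolerance = 0.05)
  expect_equal(cor(x1[-1], x1[-length(x1)]), 0.9, tolerance = 0.01)

  # channel 1 drives channel 2 with a 3-sample delay: cross-correlation
  # peaks at the imposed lag (brute-force ccf oracle)
  A <- array(0, c(3, 2, 2))
  A[3, 2, 1] <- 0.9
  cp2 <- coupling_spec(A, diag(2))
  x2 <- simulate_var(cp2, 50000, 100, 7)
  cc <- ccf(x2[, 1], x2[, 2], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(abs(cc$acf))], -3)

  # instability rejected at construction, radius reported
  expect_error(coupling_spec(array(1.05, c(1, 1, 1)), matrix(1)),
               "spectral radius")
})

test_that("phase-modulated spike trains obey the von Mises intensity model", {
  fs <- 1000
  dur <- 200
  phase <- wrap_deg(360 * 8 * (0:(dur * fs - 1)) / fs)  # ideal 8 Hz ramp

  # kappa = 0: homogeneous Poisson, count within 4*sqrt(rate*T)
  m0 <- spike_mod_spec(base_rate = 5, kappa = 0)
  s0 <- simulate_spike_train(phase, m0, fs, 11)
  expect_lt(abs(length(s0) - 5 * dur), 4 * sqrt(5 * dur))

  # kappa = 5, theta = 90: circular mean of spike phases near 90
  m5 <- spike_mod_spec(base_rate = 5, kappa = 5, pref_phase = 90)
  s5 <- simulate_spike_train(phase, m5, fs, 12)
  ph <- wrap_deg(360 * 8 * s5)
  mu <- atan2(mean(sin(ph * pi / 180)), mean(cos(ph * pi / 180))) * 180 / pi
  expect_lt(abs(mu - 90), 5)

  # marginal mean rate equals base_rate despite modulation
  expect_equal(length(s5) / dur, 5, tolerance = 0.1)

  expect_identical(simulate_spike_train(phase, m5, fs, 12), s5)
  expect_length(simulate_spike_train(phase, spike_mod_spec(0, 1), fs, 1), 0)
  expect_error(spike_mod_spec(-1, 1))
  expect_error(spike_mod_spec(1, -1))
})

test_that("sessions assemble mixing, epochs, and ground truth coherently", {
  cfg <- session_config("volume_conduction",
                        sources = list(source_spec(8, 1, 1)),
                        mixing = mixing_map(matrix(1, 3, 1)),
                        n_trials = 3, epoch_len = 2, gap_len = 1, fs = 250,
                        noise_sd = 0, channel_shank_map = c(1, 1, 2),
                        seed = 9)
  ds <- simulate_session(cfg)
  # degenerate mixing with zero noise: all channels identical
  expect_lt(max(abs(ds$recording$samples[1, ] - ds$recording$samples[3, ])),
            1e-12)
  # epochs non-overlapping, exact length, half-open
  ep <- ds$epochs
  expect_true(all(ep$end - ep$start == 500))
  o <- order(ep$start)
  expect_true(all(ep$end[o][-nrow(ep)] <= ep$start[o][-1]))
  # same config + seed: bit-identical dataset
  expect_identical(ds, simulate_session(cfg))
  # truth record present
  expect_identical(ds$truth$scenario, "volume_conduction")
  expect_equal(ncol(ds$truth$source_series), 1)

  # coupling forbidden under volume conduction
  expect_error(
    session_config("volume_conduction", sources = list(source_spec(8, 1, 1)),
                   mixing = mixing_map(matrix(1, 2, 1)),
                   coupling = coupling_spec(array(0.5, c(1, 1, 1)), matrix(1)),
                   channel_shank_map = c(1, 2)),
    "not allowed")
  expect_error(
    session_config("lagged_coupling", sources = list(source_spec(8, 1, 1)),
                   mixing = mixing_map(matrix(1, 2, 1)),
                   channel_shank_map = c(1, 2)),
    "requires")
})

test_that("run/baseline amplitude step follows the square law in power", {
  cfg <- session_config("volume_conduction",
                        sources = list(source_spec(8, 1, amplitude_run = 2,
                                                   amplitude_baseline = 1)),
                        mixing = mixing_map(matrix(1, 1, 1)),
                        n_trials = 12, epoch_len = 5, gap_len = 1, fs = 250,
                        noise_sd = 0.01, channel_shank_map = 1L, seed = 21)
  ds <- simulate_session(cfg)
  cfg_s <- spectral_config(freqs = seq(1, 20, 0.2),
                           smoothing_mode = "fixed_bandwidth",
                           smoothing_param = 1)
  run <- epoch_tensor(ds$recording, ds$epochs, "run", 1)[, 1, ]
  bl <- epoch_tensor(ds$recording, ds$epochs, "baseline", 1)[, 1, ]
  pr <- whiten_psd(multitaper_psd(run, 250, cfg_s))
  pb <- whiten_psd(multitaper_psd(bl, 250, cfg_s))
  i8 <- which.min(abs(pr$freqs - 8))
  expect_equal(pr$power[i8] / pb$power[i8], 4, tolerance = 0.35)
})

test_that("spike times stay inside the recording across a session", {
  cfg <- demo_session_config("volume_conduction", seed = 3, n_trials = 2)
  ds <- simulate_session(cfg)
  dur <- ncol(ds$recording$samples) / ds$recording$fs
  for (s in ds$spikes) {
    if (length(s)) expect_true(min(s) >= 0 && max(s) < dur)
  }
})
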