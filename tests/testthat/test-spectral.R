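fixed_cfg <- function(w = 1, k = 7, freqs = seq(1, 20, 0.2)) {
  spectral_config(freqs = freqs, n_tapers = k,
                  smoothing_mode = "fixed_bandwidth", smoothing_param = w)
}

test_that("white-noise PSD is flat and integrates to the variance", {
  set.seed(2)
  fs <- 256
  wn <- matrix(rnorm(30 * 1024, sd = 2), 30, 1024)
  est <- multitaper_psd(wn, fs, spectral_config(freqs = NULL, n_tapers = 5,
                                                smoothing_mode = "fixed_bandwidth",
                                                smoothing_param = 1))
  integral <- sum(est$power) * diff(est$freqs)[1]
  expect_equal(integral, 4, tolerance = 0.05)
  # flatness: central 90% of bins within 3x of the median
  p <- est$power[est$freqs > 5 & est$freqs < 120]
  expect_lt(max(p) / median(p), 3)
  expect_true(all(est$power >= 0))
})

test_that("a pure tone concentrates A^2/2 power at its frequency", {
  fs <- 250
  t <- (0:(5 * fs - 1)) / fs
  A <- 3
  ep <- t(replicate(4, A * sin(2 * pi * 8 * t)))
  est <- multitaper_psd(ep, fs, spectral_config(freqs = NULL, n_tapers = 5,
                                                smoothing_mode = "fixed_bandwidth",
                                                smoothing_param = 1.2))
  expect_equal(est$freqs[which.max(est$power)], 8, tolerance = 0.2)
  df <- diff(est$freqs)[1]
  around <- est$freqs > 5 & est$freqs < 11
  expect_equal(sum(est$power[around]) * df, A^2 / 2, tolerance = 0.05)
})

test_that("the 1-20 Hz display grid has 96 points in both modes", {
  set.seed(3)
  x <- matrix(rnorm(4 * 1250 * 5), 4)
  for (cfg in list(fixed_cfg(), spectral_config())) {
    est <- multitaper_psd(x, 1250, cfg)
    expect_length(est$freqs, 96)
    expect_length(est$power, 96)
  }
})

test_that("proportional smoothing reproduces a clean theta peak", {
  x <- simulate_theta_source(source_spec(8, 1, 1), 60, 250, 8)
  ep <- matrix(x, nrow = 12, byrow = TRUE)
  est <- multitaper_psd(ep, 250, spectral_config())  # 0.8*f, 7 tapers
  expect_equal(est$freqs[which.max(whiten_psd(est)$power)], 8,
               tolerance = 1.1)
})

test_that("cross-spectra are Hermitian with PSD-consistent diagonals", {
  set.seed(4)
  fs <- 250
  n_ep <- 40
  x <- matrix(rnorm(n_ep * 512), n_ep)
  tens <- array(0, c(n_ep, 2, 512))
  tens[, 1, ] <- x
  tens[, 2, ] <- x                       # identical channels
  cfg <- fixed_cfg(w = 2, k = 3, freqs = seq(5, 100, 1))
  csd <- multitaper_csd(tens, fs, cfg)
  expect_lt(max(Mod(csd$S[, 1, 2] - csd$S[, 1, 1])), 1e-12)
  expect_lt(max(Mod(csd$S[, 1, 2] - Conj(csd$S[, 2, 1]))), 1e-15)
  psd <- multitaper_psd(x, fs, cfg)
  expect_lt(max(abs(Re(csd$S[, 1, 1]) - psd$power) / psd$power), 1e-10)

  # independent channels: normalized cross-spectrum shrinks with dof
  set.seed(5)
  tens2 <- array(rnorm(n_ep * 2 * 512), c(n_ep, 2, 512))
  csd2 <- multitaper_csd(tens2, fs, cfg)
  coh <- Mod(csd2$S[, 1, 2]) / sqrt(Re(csd2$S[, 1, 1]) * Re(csd2$S[, 2, 2]))
  expect_lt(mean(coh), 3 / sqrt(n_ep * 3))
  expect_error(multitaper_csd(tens[, 1, , drop = FALSE], fs, cfg),
               "2 channels")
})

test_that("whitening multiplies by frequency squared and inverts", {
  est <- structure(list(freqs = c(1, 8, 10), power = c(1, 1, 0.5),
                        n_epochs = 1, fs = 250,
                        cfg = spectral_config(freqs = c(1, 8, 10))),
                   class = "spectral_estimate")
  w <- whiten_psd(est)
  expect_equal(w$power, c(1, 64, 50))
  expect_equal(w$power / w$freqs^2, est$power)
})

test_that("estimator variance shrinks with epochs times tapers", {
  set.seed(6)
  fs <- 200
  rel_var <- function(n_ep, k) {
    x <- matrix(rnorm(n_ep * 512), n_ep)
    est <- multitaper_psd(x, fs, spectral_config(freqs = NULL, n_tapers = k,
                                                 smoothing_mode = "fixed_bandwidth",
                                                 smoothing_param = 4))
    p <- est$power[est$freqs > 10 & est$freqs < 90]
    var(p) / mean(p)^2
  }
  v_small <- rel_var(5, 3)    # 15 degrees of freedom
  v_big <- rel_var(40, 6)     # 240 degrees of freedom
  expect_gt(v_small / v_big, 4)  # expect ~16x, allow wide stochastic slack
})

test_that("spectrogram tracks an amplitude-stepped theta source", {
  fs <- 250
  step_env <- rep(c(1, 2), each = 10 * fs)    # 10 s low, 10 s high
  x <- simulate_theta_source(source_spec(8, 1, 1), 20, fs, 10) * step_env
  sg <- spectrogram(x, fs, cfg = spectral_config(freqs = seq(2, 20, 0.5),
                                                 n_tapers = 5,
                                                 smoothing_param = 0.2),
                    window = 4, step = 2)
  row8 <- which.min(abs(sg$freqs - 8))
  lo <- sg$db[row8, sg$times < 9]
  hi <- sg$db[row8, sg$times > 12]
  expect_gt(mean(hi) - mean(lo), 4)   # 4x power step = +6 dB

  # constant signal hits the configured floor instead of -Inf
  sgc <- spectrogram(rep(1, 5 * fs), fs,
                     cfg = spectral_config(freqs = seq(2, 20, 1),
                                           n_tapers = 3,
                                           smoothing_param = 0.5),
                     window = 2, step = 1, db_floor = -120)
  expect_true(all(is.finite(sgc$db)))
  expect_true(all(sgc$db >= -120))
  expect_error(spectrogram(x, fs, window = 2, step = 0), "positive")
})
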