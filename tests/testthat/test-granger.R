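var_csd <- function(coupling, n_ep, len, fs, seed, k = 5, nw_hz = NULL) {
  x <- simulate_var(coupling, n_ep * len, fs, seed)
  nw_hz <- nw_hz %||% (3 * fs / len)
  multitaper_csd(cut_epochs(x, len), fs,
                 spectral_config(freqs = NULL, n_tapers = k,
                                 smoothing_mode = "fixed_bandwidth",
                                 smoothing_param = nw_hz))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a white identity spectrum factorizes into H = I, Sigma = I", {
  fs <- 2
  freqs <- seq(0, 1, length.out = 65)
  S <- array(0i, c(65, 2, 2))
  S[, 1, 1] <- 1; S[, 2, 2] <- 1          # one-sided density, interior = 2*s2
  S[1, , ] <- S[1, , ] / 2; S[65, , ] <- S[65, , ] / 2
  S[1, 1, 1] <- 0.5; S[1, 2, 2] <- 0.5
  S[65, 1, 1] <- 0.5; S[65, 2, 2] <- 0.5
  csd <- structure(list(freqs = freqs, S = S, fs = fs, n_epochs = 1,
                        nfft = 128, cfg = NULL),
                   class = "cross_spectral_matrix")
  f <- wilson_factorize(csd)
  expect_lt(max(Mod(f$H[, 1, 1] - 1)), 1e-8)
  expect_lt(max(Mod(f$H[, 1, 2])), 1e-8)
  expect_equal(f$Sigma, diag(2), tolerance = 1e-8)
  expect_lt(f$residual, 1e-10)
})

test_that("factorization recovers a known VAR noise covariance within 1%", {
  cp <- benchmark_var2()
  csd <- var_csd(cp, 300, 1024, 200, 21)
  f <- wilson_factorize(csd)
  expect_lt(f$residual, 1e-6)
  expect_equal(f$Sigma[1, 1], 1, tolerance = 0.01)
  expect_equal(f$Sigma[2, 2], 1, tolerance = 0.01)
  expect_lt(abs(f$Sigma[1, 2]), 0.01)
})

test_that("nonparametric Geweke spectra match the parametric oracle", {
  cp <- benchmark_var2()
  csd <- var_csd(cp, 200, 2048, 200, 22)
  dec <- granger_spectral(wilson_factorize(csd))
  oracle <- granger_parametric(cp, 200, dec$freqs)
  # compare at the spectral peak, averaged over a +/- 1 Hz window to keep
  # the comparison insensitive to single-bin estimation noise
  pkf <- oracle$freqs[which.max(oracle$f_x2y)]
  win <- abs(oracle$freqs - pkf) <= 1
  expect_equal(mean(dec$f_x2y[win]), mean(oracle$f_x2y[win]),
               tolerance = 0.05)
  pk <- which.max(oracle$f_x2y)
  expect_lt(dec$f_y2x[pk], 0.05 * dec$f_x2y[pk])
  # identity holds pointwise
  expect_lt(max(abs(dec$f_total - dec$f_x2y - dec$f_y2x - dec$f_inst)),
            1e-6)
  expect_true(all(dec$f_x2y >= 0) && all(dec$f_y2x >= 0) &&
                all(dec$f_inst >= 0))
})

test_that("independent channels yield a near-null decomposition", {
  cp0 <- coupling_spec(array(0, c(1, 2, 2)), diag(2))
  csd <- var_csd(cp0, 200, 512, 100, 23)
  dec <- suppressMessages(granger_spectral(wilson_factorize(csd)))
  # small-sample bias of GC under the null is ~ 1/dof per direction
  expect_lt(stats::quantile(dec$f_x2y, 0.95), 0.02)
  expect_lt(stats::quantile(dec$f_y2x, 0.95), 0.02)
  expect_lt(stats::quantile(dec$f_total, 0.95), 0.05)
})

test_that("the decomposition is invariant to channel rescaling", {
  cp <- benchmark_var2()
  x <- simulate_var(cp, 100 * 512, 100, 24)
  cfg <- spectral_config(freqs = NULL, n_tapers = 3,
                         smoothing_mode = "fixed_bandwidth",
                         smoothing_param = 2 * 100 / 512)
  d1 <- granger_spectral(wilson_factorize(
    multitaper_csd(cut_epochs(x, 512), 100, cfg)))
  x2 <- x
  x2[, 1] <- x2[, 1] * 50
  x2[, 2] <- x2[, 2] * 0.02
  d2 <- granger_spectral(wilson_factorize(
    multitaper_csd(cut_epochs(x2, 512), 100, cfg)))
  expect_lt(max(abs(d1$f_x2y - d2$f_x2y)), 1e-8)
  expect_lt(max(abs(d1$f_inst - d2$f_inst)), 1e-7)
})

test_that("nonparametric estimates converge toward the oracle with epochs", {
  cp <- benchmark_var2()
  err_at <- function(n_ep, seed) {
    csd <- var_csd(cp, n_ep, 512, 200, seed, k = 3, nw_hz = 2 * 200 / 512)
    dec <- suppressMessages(granger_spectral(wilson_factorize(csd)))
    oracle <- granger_parametric(cp, 200, dec$freqs)
    pk <- which.max(oracle$f_x2y)
    abs(dec$f_x2y[pk] - oracle$f_x2y[pk])
  }
  e_small <- mean(vapply(1:3, function(i) err_at(25, 30 + i), numeric(1)))
  e_big <- mean(vapply(1:3, function(i) err_at(200, 40 + i), numeric(1)))
  expect_lt(e_big, e_small)
})

test_that("band shares sum to one and follow the scenario ground truth", {
  # common-source scenario: instantaneous term dominates at the source peak
  tens <- common_source_tensor(40, 5, 250, noise_sd = 0.1, seed = 31)
  cfg <- spectral_config(freqs = NULL, n_tapers = 7,
                         smoothing_mode = "fixed_bandwidth",
                         smoothing_param = 1)
  dec <- suppressMessages(granger_spectral(wilson_factorize(
    multitaper_csd(tens, 250, cfg))))
  rep_theta <- decomposition_report(dec, c(6, 10))
  expect_equal(rep_theta$share_inst + rep_theta$share_x2y +
                 rep_theta$share_y2x, 1, tolerance = 1e-9)
  i8 <- which.min(abs(dec$freqs - 8))
  expect_gte(dec$f_inst[i8] / dec$f_total[i8], 0.9)
  expect_lte(dec$f_x2y[i8] / dec$f_total[i8], 0.1)
  expect_lte(dec$f_y2x[i8] / dec$f_total[i8], 0.1)

  # directional scenario: the driving direction dominates
  cp <- benchmark_var2(0.25)
  csd <- var_csd(cp, 100, 512, 200, 32)
  decd <- suppressMessages(granger_spectral(wilson_factorize(csd)))
  oracle <- granger_parametric(cp, 200, decd$freqs)
  band <- c(30, 50)
  repd <- decomposition_report(decd, band)
  expect_gt(repd$share_x2y, repd$share_y2x)
  expect_error(decomposition_report(decd, c(300, 400)), "empty")
})

test_that("degenerate spectra are rejected with the offending frequency", {
  freqs <- seq(0, 1, length.out = 33)
  S <- array(0i, c(33, 2, 2))
  S[, 1, 1] <- 1; S[, 2, 2] <- 1
  S[5, 2, 2] <- -1   # not positive definite at freqs[5]
  csd <- structure(list(freqs = freqs, S = S, fs = 2, n_epochs = 1,
                        nfft = 64, cfg = NULL),
                   class = "cross_spectral_matrix")
  expect_error(wilson_factorize(csd), "positive definite")
})
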