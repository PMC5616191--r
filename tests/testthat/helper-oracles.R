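# Independent oracles used across tests.

# O(n^2) pairwise phase consistency by direct enumeration of all pairs
brute_force_ppc <- function(phases_deg) {
  n <- length(phases_deg)
  rad <- phases_deg * pi / 180
  acc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) acc <- acc + cos(rad[i] - rad[j])
  }
  2 * acc / (n * (n - 1))
}

# expected PPC of a von Mises sample: (I1(kappa)/I0(kappa))^2
vonmises_ppc_theory <- function(kappa) {
  (besselI(kappa, 1, expon.scaled = TRUE) /
     besselI(kappa, 0, expon.scaled = TRUE))^2
}

# cut a long multichannel series [n x p] into [n_epochs x p x len]
cut_epochs <- function(x, len) {
  x <- as.matrix(x)
  n_ep <- floor(nrow(x) / len)
  arr <- array(0, c(n_ep, ncol(x), len))
  for (i in seq_len(n_ep)) {
    arr[i, , ] <- t(x[((i - 1) * len + 1):(i * len), , drop = FALSE])
  }
  arr
}

# two channels observing one narrowband source with equal unit gains plus
# independent white noise; returns epoch tensor
common_source_tensor <- function(n_epochs, epoch_len_s, fs, noise_sd,
                                 seed, f0 = 8, bw = 1) {
  n <- n_epochs * round(epoch_len_s * fs)
  s <- simulate_theta_source(source_spec(f0, bw, 1), n / fs, fs, seed)
  set.seed(seed + 1)
  x <- cbind(s + rnorm(n, sd = noise_sd), s + rnorm(n, sd = noise_sd))
  cut_epochs(x, round(epoch_len_s * fs))
}

# classic bivariate benchmark: stable AR(2) oscillators, channel 1 driving
# channel 2 at lag 1
benchmark_var2 <- function(c12 = 0.2) {
  A <- array(0, c(2, 2, 2))
  A[1, 1, 1] <- 0.55; A[2, 1, 1] <- -0.8
  A[1, 2, 2] <- 0.55; A[2, 2, 2] <- -0.8
  A[1, 2, 1] <- c12
  coupling_spec(A, diag(2))
}
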