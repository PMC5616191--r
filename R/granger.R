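# Nonparametric spectral Granger causality: Wilson factorization of the
# cross-spectral matrix into a minimum-phase transfer function and a noise
# covariance, followed by the Geweke decomposition of total interdependence
# into two directed terms and an instantaneous term.

# 2x2 complex matrix field helpers: a field is a list(a11, a12, a21, a22) of
# complex vectors indexed by frequency.
.m2 <- function(a11, a12, a21, a22) list(a11 = a11, a12 = a12, a21 = a21,
                                         a22 = a22)
.m2_mult <- function(A, B) {
  .m2(A$a11 * B$a11 + A$a12 * B$a21,
      A$a11 * B$a12 + A$a12 * B$a22,
      A$a21 * B$a11 + A$a22 * B$a21,
      A$a21 * B$a12 + A$a22 * B$a22)
}
.m2_inv <- function(A) {
  det <- A$a11 * A$a22 - A$a12 * A$a21
  .m2(A$a22 / det, -A$a12 / det, -A$a21 / det, A$a11 / det)
}
.m2_ctrans <- function(A) .m2(Conj(A$a11), Conj(A$a21), Conj(A$a12),
                              Conj(A$a22))

#' Wilson spectral matrix factorization
#'
#' Factorizes a Hermitian positive-definite cross-spectral matrix given on a
#' uniform grid spanning `[0, fs/2]` as `S(f) = H(f) Sigma H(f)^*` with
#' `H` minimum-phase and `H(0)` normalized through the Cholesky factor of
#' `Sigma`, using Wilson's iterative algorithm. This is the step that lets
#' Granger causality be estimated without fitting an autoregressive model.
#'
#' @param csd A `cross_spectral_matrix` on the full FFT grid (build it with
#'   `multitaper_csd(..., cfg = spectral_config(freqs = NULL, smoothing_mode
#'   = "fixed_bandwidth", ...))`).
#' @param tol Convergence tolerance on the relative update of the spectral
#'   factor (default 1e-12; convergence is quadratic, so the final iterate
#'   sits at machine precision).
#' @param max_iter Maximum iterations (default 1000).
#' @return A `factorization_result`: list with `freqs`, `H` (complex array
#'   `[n_freq x p x p]`), `Sigma` (innovation covariance), `residual`
#'   (maximum relative Frobenius reconstruction error over frequencies),
#'   `n_iter`, and `S_model` (the reconstructed spectrum `H Sigma H^*`).
#' @export
wilson_factorize <- function(csd, tol = 1e-12, max_iter = 1000) {
  stopifnot(inherits(csd, "cross_spectral_matrix"))
  freqs <- csd$freqs
  nh <- length(freqs)
  p <- dim(csd$S)[2]
  step <- diff(freqs)
  if (max(abs(step - step[1])) > 1e-6 * step[1] || abs(freqs[1]) > 1e-9 ||
      abs(freqs[nh] - csd$fs / 2) > 1e-6) {
    stopf("factorization needs a uniform frequency grid spanning [0, fs/2]")
  }
  if (p != 2) {
    stopf("spectral factorization is implemented for channel pairs (p = 2)")
  }
  nfft <- 2L * (nh - 1L)

  # undo the one-sided density convention -> two-sided values on [0, fs/2]
  s2 <- csd$S
  s2[2:(nh - 1), , ] <- s2[2:(nh - 1), , ] / 2

  # prenormalize channels to unit mean power: makes the iteration (and its
  # stopping rule) exactly equivariant under channel rescaling
  ch_scale <- sqrt(c(mean(Re(s2[, 1, 1])), mean(Re(s2[, 2, 2]))))
  if (any(!is.finite(ch_scale)) || any(ch_scale <= 0)) {
    stopf("nonpositive channel power; cannot factorize")
  }
  for (i in 1:2) for (j in 1:2) {
    s2[, i, j] <- s2[, i, j] / (ch_scale[i] * ch_scale[j])
  }

  # positive-definiteness check (2x2: real diagonal, positive determinant)
  d11 <- Re(s2[, 1, 1]); d22 <- Re(s2[, 2, 2])
  det2 <- d11 * d22 - Mod(s2[, 1, 2])^2
  bad <- which(d11 <= 0 | d22 <= 0 | det2 <= 0)
  if (length(bad)) {
    stopf("cross-spectral matrix not positive definite at %g Hz",
          freqs[bad[1]])
  }

  # extend to the full circle: S(-f) = Conj(S(f))
  full_idx <- function(comp) {
    v <- complex(length.out = nfft)
    v[1:nh] <- comp
    v[(nh + 1):nfft] <- Conj(comp[(nh - 1):2])
    v
  }
  S <- .m2(full_idx(s2[, 1, 1]), full_idx(s2[, 1, 2]),
           full_idx(s2[, 2, 1]), full_idx(s2[, 2, 2]))

  # init: psi(f) = chol of the frequency-averaged spectrum
  g0 <- matrix(c(mean(Re(S$a11)), mean(Re(S$a21)),
                 mean(Re(S$a12)), mean(Re(S$a22))), 2, 2)
  g0 <- (g0 + t(g0)) / 2
  h0 <- chol(g0)
  ones <- rep(1 + 0i, nfft)
  psi <- .m2(h0[1, 1] * ones, h0[1, 2] * ones, h0[2, 1] * ones,
             h0[2, 2] * ones)

  plus_op <- function(G) {
    keep <- nh  # lags 0 .. nfft/2
    for (nm in names(G)) {
      gam <- stats::fft(G[[nm]], inverse = TRUE) / nfft
      gam[(keep + 1):nfft] <- 0
      G[[nm]] <- gam
    }
    # the lag-0 and lag-nfft/2 coefficients are Hermitian and appear once on
    # the circle: split each as p + p^H = gamma (halve the diagonal, keep
    # the upper part, drop the lower part)
    for (l0 in c(1L, keep)) {
      G$a11[l0] <- 0.5 * G$a11[l0]
      G$a21[l0] <- 0
      G$a22[l0] <- 0.5 * G$a22[l0]
    }
    for (nm in names(G)) G[[nm]] <- stats::fft(G[[nm]])
    G
  }

  n_iter <- max_iter
  for (it in seq_len(max_iter)) {
    ipsi <- .m2_inv(psi)
    g <- .m2_mult(.m2_mult(ipsi, S), .m2_ctrans(ipsi))
    g$a11 <- g$a11 + 1
    g$a22 <- g$a22 + 1
    gp <- plus_op(g)
    psi_new <- .m2_mult(psi, gp)
    num <- max(abs(psi_new$a11 - psi$a11), abs(psi_new$a12 - psi$a12),
               abs(psi_new$a21 - psi$a21), abs(psi_new$a22 - psi$a22))
    den <- max(abs(psi$a11), abs(psi$a12), abs(psi$a21), abs(psi$a22))
    psi <- psi_new
    if (num / den < tol) { n_iter <- it; break }
    if (it == max_iter) {
      stopf("Wilson factorization did not converge in %d iterations (last relative update %.3g)",
            max_iter, num / den)
    }
  }

  # noise covariance and transfer function from the zero-lag coefficient
  A0 <- matrix(c(mean(Re(psi$a11)), mean(Re(psi$a21)),
                 mean(Re(psi$a12)), mean(Re(psi$a22))), 2, 2)
  Sigma_density <- A0 %*% t(A0)
  iA0 <- solve(A0)
  Hf <- .m2_mult(psi, .m2(iA0[1, 1] + 0i, iA0[1, 2] + 0i,
                          iA0[2, 1] + 0i, iA0[2, 2] + 0i))
  # reconstruction and residual on the half grid
  rec <- .m2_mult(psi, .m2_ctrans(psi))
  res_num <- sqrt(Mod(rec$a11 - S$a11)^2 + Mod(rec$a12 - S$a12)^2 +
                    Mod(rec$a21 - S$a21)^2 + Mod(rec$a22 - S$a22)^2)
  res_den <- max(sqrt(Mod(S$a11)^2 + Mod(S$a12)^2 + Mod(S$a21)^2 +
                        Mod(S$a22)^2))
  residual <- max(res_num) / res_den

  # undo the channel prenormalization: S -> D S D, H -> D H D^-1,
  # Sigma -> D Sigma D; signal-unit innovation covariance rescales the
  # density by fs
  Sigma_density <- diag(ch_scale) %*% Sigma_density %*% diag(ch_scale)
  Sigma <- Sigma_density * csd$fs
  H <- array(0i, c(nh, 2, 2))
  H[, 1, 1] <- Hf$a11[1:nh]
  H[, 1, 2] <- Hf$a12[1:nh] * ch_scale[1] / ch_scale[2]
  H[, 2, 1] <- Hf$a21[1:nh] * ch_scale[2] / ch_scale[1]
  H[, 2, 2] <- Hf$a22[1:nh]
  S_model <- array(0i, c(nh, 2, 2))
  S_model[, 1, 1] <- rec$a11[1:nh] * ch_scale[1]^2
  S_model[, 1, 2] <- rec$a12[1:nh] * ch_scale[1] * ch_scale[2]
  S_model[, 2, 1] <- rec$a21[1:nh] * ch_scale[1] * ch_scale[2]
  S_model[, 2, 2] <- rec$a22[1:nh] * ch_scale[2]^2

  structure(list(freqs = freqs, H = H, Sigma = Sigma,
                 Sigma_density = Sigma_density, residual = residual,
                 n_iter = n_iter, S_model = S_model, fs = csd$fs),
            class = "factorization_result")
}

# Geweke decomposition from transfer function, noise covariance and spectrum
.geweke <- function(freqs, H, Sigma, S, fs, display_freqs = NULL) {
  sxx <- Re(S[, 1, 1]); syy <- Re(S[, 2, 2])
  cross2 <- Mod(S[, 1, 2])^2
  coh2 <- pmin(cross2 / (sxx * syy), 1)
  f_total <- -log1p(-coh2)
  f_total[coh2 >= 1] <- Inf

  s_yy_c <- Sigma[2, 2] - Sigma[1, 2]^2 / Sigma[1, 1]  # y-noise given x
  s_xx_c <- Sigma[1, 1] - Sigma[1, 2]^2 / Sigma[2, 2]  # x-noise given y
  f_y2x <- log(sxx / (sxx - s_yy_c * Mod(H[, 1, 2])^2))
  f_x2y <- log(syy / (syy - s_xx_c * Mod(H[, 2, 1])^2))
  f_y2x <- pmax(f_y2x, 0)
  f_x2y <- pmax(f_x2y, 0)
  f_inst <- f_total - f_x2y - f_y2x

  n_clip <- sum(is.finite(f_inst) & f_inst < 0)
  n_clip_hard <- sum(is.finite(f_inst) & f_inst < -1e-8)
  if (n_clip_hard > 0) {
    message(sprintf("instantaneous term clipped to 0 at %d frequencies (min %.3g)",
                    n_clip_hard, min(f_inst[is.finite(f_inst)])))
  }
  f_inst <- pmax(f_inst, 0)
  # keep the pointwise identity exact after clipping
  f_total <- f_x2y + f_y2x + f_inst

  out <- list(freqs = freqs, f_total = f_total, f_x2y = f_x2y,
              f_y2x = f_y2x, f_inst = f_inst, fs = fs)
  if (!is.null(display_freqs)) {
    idx <- nearest_index(display_freqs, freqs)
    out$freqs <- display_freqs
    for (nm in c("f_total", "f_x2y", "f_y2x", "f_inst")) {
      out[[nm]] <- out[[nm]][idx]
    }
  }
  structure(c(out, list(n_clipped = n_clip)), class = "granger_decomposition")
}

#' Spectral Granger decomposition from a factorized cross-spectrum
#'
#' Computes the Geweke measures at every frequency: the two directed terms
#' `f_x2y(f) = ln(S_yy / (S_yy - (Sigma_xx - Sigma_xy^2/Sigma_yy) |H_yx|^2))`
#' (and symmetrically `f_y2x`), the total interdependence
#' `f_total(f) = -ln(1 - |C_xy(f)|^2)` from the model coherence, and the
#' instantaneous term `f_inst = f_total - f_x2y - f_y2x`. Tiny negative
#' values of the instantaneous term (rounding) are clipped to zero and
#' counted; the identity `f_total = f_x2y + f_y2x + f_inst` then holds
#' pointwise by construction.
#'
#' @param fact A `factorization_result` from [wilson_factorize()].
#' @param pair Channel indices `(x, y)`; with the default `c(1, 2)` the
#'   factorized pair is used as-is (the factorization is bivariate).
#' @param display_freqs Optional grid (e.g. `seq(1, 20, 0.2)`) onto which
#'   the full-grid decomposition is sampled by nearest bin.
#' @return A `granger_decomposition`: `freqs`, `f_total`, `f_x2y`, `f_y2x`,
#'   `f_inst` (all nonnegative; infinities where coherence reaches 1 are
#'   flagged by the value itself), and `n_clipped`.
#' @export
granger_spectral <- function(fact, pair = c(1, 2), display_freqs = NULL) {
  stopifnot(inherits(fact, "factorization_result"))
  if (!identical(sort(pair), c(1, 2))) {
    stopf("the factorization is bivariate; pair must be a permutation of c(1, 2)")
  }
  H <- fact$H; S <- fact$S_model; Sigma <- fact$Sigma_density
  if (pair[1] == 2) {  # swap roles of x and y
    H <- H[, 2:1, 2:1, drop = FALSE]
    S <- S[, 2:1, 2:1, drop = FALSE]
    Sigma <- Sigma[2:1, 2:1]
  }
  .geweke(fact$freqs, H, Sigma, S, fact$fs, display_freqs)
}

#' Closed-form Geweke spectrum of a known VAR
#'
#' Parametric reference: builds the transfer function directly from the true
#' autoregressive coefficients, `H(f) = (I - sum_k A_k e^(-2 pi i f k / fs))^(-1)`,
#' the spectrum `S = H Sigma H^*`, and evaluates the same Geweke formulas.
#' Used as the analytic benchmark that nonparametric estimates converge to.
#'
#' @param coupling A [coupling_spec()] with two channels.
#' @param fs Sampling rate in Hz.
#' @param freqs Frequencies at which to evaluate, in Hz.
#' @param pair Channel indices `(x, y)` (default `c(1, 2)`).
#' @return A `granger_decomposition` (see [granger_spectral()]).
#' @export
granger_parametric <- function(coupling, fs, freqs, pair = c(1, 2)) {
  stopifnot(inherits(coupling, "coupling_spec"))
  A <- coupling$var_coeffs
  p <- dim(A)[2]
  if (p != 2) stopf("parametric Geweke spectrum implemented for 2 channels")
  nf <- length(freqs)
  H <- array(0i, c(nf, 2, 2))
  S <- array(0i, c(nf, 2, 2))
  Sigma <- coupling$noise_cov
  for (fi in seq_len(nf)) {
    Af <- diag(2) + 0i
    for (k in seq_len(dim(A)[1])) {
      lag <- k * coupling$lag_step
      Af <- Af - A[k, , ] * exp(-2i * pi * freqs[fi] * lag / fs)
    }
    Hf <- solve(Af)
    H[fi, , ] <- Hf
    S[fi, , ] <- Hf %*% Sigma %*% Conj(t(Hf))
  }
  if (pair[1] == 2) {
    H <- H[, 2:1, 2:1, drop = FALSE]
    S <- S[, 2:1, 2:1, drop = FALSE]
    Sigma <- Sigma[2:1, 2:1]
  }
  .geweke(freqs, H, Sigma, S, fs)
}

#' Band-integrated shares of the Geweke decomposition
#'
#' Integrates each component over a frequency band and normalizes by the
#' integrated total interdependence; the three shares sum to 1.
#'
#' @param dec A `granger_decomposition`.
#' @param band Frequency interval `c(lo, hi)` in Hz.
#' @return List with `share_inst`, `share_x2y`, `share_y2x`, `band`, and
#'   `defined` (`FALSE` when the band total is numerically zero, in which
#'   case the shares are `NA`).
#' @export
decomposition_report <- function(dec, band) {
  stopifnot(inherits(dec, "granger_decomposition"))
  sel <- dec$freqs >= band[1] & dec$freqs <= band[2]
  if (!any(sel)) stopf("band [%g, %g] Hz is empty on this grid", band[1],
                       band[2])
  fin <- sel & is.finite(dec$f_total)
  n_inf <- sum(sel) - sum(fin)
  if (n_inf > 0) {
    message(sprintf("decomposition_report: %d frequencies with infinite total excluded",
                    n_inf))
  }
  tot <- sum(dec$f_total[fin])
  if (tot < 1e-12) {
    return(list(share_inst = NA_real_, share_x2y = NA_real_,
                share_y2x = NA_real_, band = band, defined = FALSE))
  }
  list(share_inst = sum(dec$f_inst[fin]) / tot,
       share_x2y = sum(dec$f_x2y[fin]) / tot,
       share_y2x = sum(dec$f_y2x[fin]) / tot,
       band = band, defined = TRUE)
}
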