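# Shared helpers: circular arithmetic, analytic signal, seeded evaluation.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded generators do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Wrap angles in degrees into (-180, 180]
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# circular mean of angles in degrees, result in (-180, 180]
circ_mean_deg <- function(phases) {
  rad <- phases * pi / 180
  wrap_deg(atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi)
}

# mean resultant length of angles in degrees
circ_r <- function(phases) {
  rad <- phases * pi / 180
  sqrt(mean(cos(rad))^2 + mean(sin(rad))^2)
}

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length; its argument is the
#'   instantaneous phase (0 at a local oscillation peak for a cosine-like
#'   signal), its modulus the instantaneous amplitude.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) return(complex(real = x, imaginary = rep(0, n)))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

# nearest index of `grid` for each value in `x`
nearest_index <- function(x, grid) {
  vapply(x, function(v) which.min(abs(grid - v)), integer(1))
}
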