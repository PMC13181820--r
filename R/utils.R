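#' @importFrom stats fft median sd qt pt rnorm runif rpois quantile approx convolve cor t.test
#' @importFrom utils head tail
NULL

#' Time axis of an epoch grid
#'
#' Sample times in ms for an epoch spanning `span` (half-open, `[start, end)`)
#' at sampling rate `fs` Hz. Time 0 is the alignment event (the left-hand
#' force peak in the motor task this package was written around).
#'
#' @param span numeric length-2, epoch start/end in ms.
#' @param fs sampling rate in Hz.
#' @return numeric vector of sample times (ms).
#' @export
epoch_times <- function(span = c(-2000, 2000), fs = 256) {
  stopifnot(length(span) == 2, span[1] < span[2], fs > 0)
  dt <- 1000 / fs
  n <- round((span[2] - span[1]) / dt)
  span[1] + (seq_len(n) - 1) * dt
}

# Analytic signal via frequency-domain construction (one-sided spectrum).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Amplitude envelope of a real signal
#'
#' Magnitude of the analytic signal (Hilbert envelope).
#'
#' @param x numeric vector.
#' @return non-negative numeric vector, same length.
#' @export
hilbert_envelope <- function(x) Mod(analytic_signal(x))

# Gaussian noise with power spectral density proportional to f^(-exponent),
# generated by shaping white noise in the frequency domain. DC is zeroed.
pink_noise <- function(n, exponent = 1, scale = 1) {
  if (exponent == 0) return(scale * stats::rnorm(n))
  nf <- floor(n / 2)
  f <- seq_len(nf)
  amp <- f^(-exponent / 2)
  re <- stats::rnorm(nf) * amp
  im <- stats::rnorm(nf) * amp
  spec <- complex(real = re, imaginary = im)
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Re(spec[nf]), imaginary = 0)
    if (nf > 1) full[n:(n - nf + 2)] <- Conj(spec[1:(nf - 1)])
  } else {
    full[n:(n - nf + 1)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x / stats::sd(x)
  scale * x
}

# Zero-padded convolution of x with a (normalized) Gaussian kernel,
# sigma in samples; kernel truncated at +/- 4 sigma.
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(numeric(half), x, numeric(half))
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

# Indices of samples falling in the half-open window [w[1], w[2]) in ms.
window_idx <- function(times, w) which(times >= w[1] & times < w[2])

# Sample (n-1) SD, NA if fewer than 2 values.
sample_sd <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
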