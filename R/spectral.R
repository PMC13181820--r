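#' Morlet wavelet specification
#'
#' Frequencies and cycle scaling for the time-frequency decomposition.
#' The number of cycles grows nonlinearly with frequency,
#' `cycles(f) = c_min + (c_max - c_min) * ((f - f_min)/(f_max - f_min))^gamma`,
#' trading temporal resolution at low beta for frequency resolution at high
#' beta.
#'
#' @param freqs analysis frequencies in Hz (default 15-30 in 1 Hz steps).
#' @param c_min,c_max cycle counts at the lowest / highest frequency.
#' @param gamma exponent of the power-law interpolation.
#' @param analysis_span ms window the TFR is evaluated on (edge-guarded).
#' @return a `wavelet_spec` object.
#' @export
wavelet_spec <- function(freqs = 15:30, c_min = 4, c_max = 8, gamma = 0.7,
                         analysis_span = c(-750, 1500)) {
  stopifnot(!is.unsorted(freqs), c_min <= c_max, gamma > 0,
            analysis_span[1] < analysis_span[2])
  structure(list(freqs = freqs, c_min = c_min, c_max = c_max, gamma = gamma,
                 analysis_span = analysis_span),
            class = "wavelet_spec")
}

wavelet_cycles <- function(spec) {
  f <- spec$freqs
  if (length(f) == 1 || max(f) == min(f)) return(rep(spec$c_min, length(f)))
  x <- (f - min(f)) / (max(f) - min(f))
  spec$c_min + (spec$c_max - spec$c_min) * x^spec$gamma
}

# Complex Morlet wavelet sampled at fs, sigma_t = cycles/(2*pi*f), support
# +/- 3.5 sigma_t, L2-normalized.
morlet_wavelet <- function(freq, cycles, fs) {
  sigma_t <- cycles / (2 * pi * freq)
  half_n <- ceiling(3.5 * sigma_t * fs)
  t <- (-half_n:half_n) / fs
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * freq * t)
  w / sqrt(sum(Mod(w)^2))
}

#' Morlet wavelet time-frequency representation
#'
#' Convolves every trial with complex Morlet wavelets (FFT convolution),
#' squares the magnitude, and averages over trials. Power is only returned
#' on the analysis span, and the epoch must extend beyond that span by each
#' wavelet's half support (edge-effect guard).
#'
#' @param epochs an [epoch_array].
#' @param spec a [wavelet_spec].
#' @return a `tfr_result`: `power` (freq x time), `freqs`, `times`,
#'   `normalized` flag, `n_trials`.
#' @export
morlet_tfr <- function(epochs, spec = wavelet_spec()) {
  fs <- epochs$fs
  times <- epochs$times
  cyc <- wavelet_cycles(spec)
  # edge guard: analysis span plus the widest wavelet half-support must fit
  guard_ms <- max(vapply(seq_along(spec$freqs), function(i) {
    3.5 * cyc[i] / (2 * pi * spec$freqs[i]) * 1000
  }, numeric(1)))
  lo_need <- spec$analysis_span[1] - guard_ms
  hi_need <- spec$analysis_span[2] + guard_ms
  if (times[1] > lo_need || times[length(times)] < hi_need) {
    stop(sprintf(
      "epoch [%g, %g] ms too short for analysis span [%g, %g] ms plus %.0f ms wavelet guard",
      times[1], times[length(times)], spec$analysis_span[1],
      spec$analysis_span[2], guard_ms))
  }
  keep <- window_idx(times, spec$analysis_span)
  n <- length(times)
  nt <- nrow(epochs$data)
  pow <- matrix(0, length(spec$freqs), length(keep))
  for (fi in seq_along(spec$freqs)) {
    w <- morlet_wavelet(spec$freqs[fi], cyc[fi], fs)
    lw <- length(w)
    nfft <- stats::nextn(n + lw - 1, 2)
    W <- stats::fft(c(w, complex(real = numeric(nfft - lw))))
    shift <- (lw - 1) / 2
    acc <- numeric(length(keep))
    for (tr in seq_len(nt)) {
      X <- stats::fft(c(epochs$data[tr, ], numeric(nfft - n)))
      conv <- stats::fft(X * W, inverse = TRUE) / nfft
      centered <- conv[(1 + shift):(n + shift)]
      acc <- acc + Mod(centered[keep])^2
    }
    pow[fi, ] <- acc / nt
  }
  structure(list(power = pow, freqs = spec$freqs, times = times[keep],
                 normalized = FALSE, n_trials = nt),
            class = "tfr_result")
}

#' Session-relative TFR normalization
#'
#' Divides each frequency row by its mean over the whole analysis span (the
#' session-specific mean), so every row of the output has mean exactly 1.
#' This whole-epoch relative baseline makes power comparable across sessions.
#'
#' @param tfr an un-normalized `tfr_result`.
#' @return normalized `tfr_result`.
#' @export
relative_normalize <- function(tfr) {
  stopifnot(inherits(tfr, "tfr_result"))
  if (isTRUE(tfr$normalized)) stop("TFR is already normalized")
  row_means <- rowMeans(tfr$power)
  if (any(row_means == 0)) stop("zero mean power row: cannot normalize")
  tfr$power <- tfr$power / row_means
  tfr$normalized <- TRUE
  tfr
}

#' Individual peak beta frequency
#'
#' Averages normalized power over a post-movement window and returns the
#' frequency attaining the maximum; ties break toward the lower frequency.
#' The estimate from a reference session is meant to be reused across that
#' subject's sessions.
#'
#' @param tfr a normalized `tfr_result` covering the window.
#' @param window ms pair (default 0-1000, where beta is most prominent).
#' @return list: `peak_freq` (Hz), `window`, `profile` (per-frequency mean
#'   power).
#' @export
estimate_peak_beta <- function(tfr, window = c(0, 1000)) {
  stopifnot(inherits(tfr, "tfr_result"))
  idx <- window_idx(tfr$times, window)
  if (!length(idx)) stop("window outside TFR time range")
  profile <- rowMeans(tfr$power[, idx, drop = FALSE])
  peak <- tfr$freqs[which.max(profile)]   # which.max takes the first tie
  list(peak_freq = peak, window = window,
       profile = stats::setNames(profile, tfr$freqs))
}

#' Beta ERD/ERS time course and window means
#'
#' Band-mean relative power versus time, with summary means over the
#' movement (-400 to 250 ms) and post-movement (250 to 1000 ms) windows.
#' Values below 1 indicate desynchronization (ERD) relative to the session
#' mean; values above 1 indicate synchronization (ERS, the post-movement
#' rebound).
#'
#' @param tfr a normalized `tfr_result`.
#' @param band Hz pair delimiting the band (inclusive; default 15-30).
#' @param movement,postmove summary windows in ms.
#' @return list: `times`, `course`, `movement_mean`, `postmove_mean`.
#' @export
erd_ers_course <- function(tfr, band = c(15, 30),
                           movement = c(-400, 250), postmove = c(250, 1000)) {
  stopifnot(inherits(tfr, "tfr_result"), isTRUE(tfr$normalized))
  rows <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  if (!length(rows)) stop("band contains no analysis frequency")
  course <- colMeans(tfr$power[rows, , drop = FALSE])
  wmean <- function(w) {
    idx <- window_idx(tfr$times, w)
    if (!length(idx)) stop("summary window outside TFR time range")
    mean(course[idx])
  }
  list(times = tfr$times, course = course,
       movement_mean = wmean(movement), postmove_mean = wmean(postmove))
}
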