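#' Analysis window set
#'
#' The three trial-aligned analysis windows used throughout the burst
#' metrics, all relative to the alignment event at 0 ms and half-open
#' `[start, end)`: Baseline (-1750 to -750 ms), Movement (-750 to 250 ms)
#' and Post-movement (250 to 1250 ms).
#'
#' @param baseline,movement,postmove numeric length-2 windows in ms.
#' @return a named list of windows with class `window_set`.
#' @export
window_set <- function(baseline = c(-1750, -750),
                       movement = c(-750, 250),
                       postmove = c(250, 1250)) {
  w <- list(baseline = baseline, movement = movement, postmove = postmove)
  for (x in w) stopifnot(length(x) == 2, x[1] < x[2])
  ord <- order(vapply(w, `[`, numeric(1), 1))
  w <- w[ord]
  for (i in seq_len(length(w) - 1)) {
    if (w[[i]][2] > w[[i + 1]][1]) stop("analysis windows must not overlap")
  }
  structure(w, class = "window_set")
}

#' Epoched single-trial time series
#'
#' Container for trials x samples data from one subject/session/region,
#' time-locked so 0 ms is the alignment event.
#'
#' @param data numeric matrix, trials x samples.
#' @param times sample times in ms (length = ncol(data)).
#' @param fs sampling rate, Hz.
#' @param meta named list of attributes (subject, session, region, seed, ...).
#' @return an `epoch_array` object.
#' @export
epoch_array <- function(data, times, fs, meta = list()) {
  stopifnot(is.matrix(data), length(times) == ncol(data))
  dt <- diff(times)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-6) {
    stop("non-uniform sampling in time axis")
  }
  structure(list(data = data, times = times, fs = fs, meta = meta),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  cat(sprintf("<epoch_array> %d trials x %d samples, %g Hz, t = [%g, %g) ms\n",
              nrow(x$data), ncol(x$data), x$fs, x$times[1],
              x$times[length(x$times)] + 1000 / x$fs))
  invisible(x)
}

#' Beta amplitude envelope of epoched data
#'
#' Bandpass filters each trial around a centre frequency (zero-phase
#' Butterworth, `filtfilt`), takes the Hilbert-envelope per trial, and
#' normalizes by the session-wide mean envelope amplitude so that the
#' session mean of the returned envelope is exactly 1. A per-trial-mean
#' normalization variant is available via `normalize = "trial"`.
#'
#' @param epochs an [epoch_array].
#' @param center_freq centre frequency in Hz (e.g. the individual peak beta
#'   frequency).
#' @param halfwidth filter half-bandwidth in Hz (default 3: peak +/- 3 Hz).
#' @param order Butterworth order (applied twice by filtfilt).
#' @param normalize `"session"` (divide all samples by the session-wide mean,
#'   the default, preserving across-trial amplitude differences) or `"trial"`
#'   (divide each trial by its own mean) or `"none"`.
#' @return an `envelope_array`: list with `env` (trials x samples matrix),
#'   `times`, `fs`, `center_freq`, `halfwidth`, `normalization`, `norm_factor`.
#' @export
extract_envelope <- function(epochs, center_freq, halfwidth = 3, order = 4,
                             normalize = c("session", "trial", "none")) {
  normalize <- match.arg(normalize)
  fs <- epochs$fs
  nyq <- fs / 2
  lo <- center_freq - halfwidth
  hi <- center_freq + halfwidth
  if (lo <= 0 || hi >= nyq) {
    stop(sprintf("band [%g, %g] Hz must lie strictly inside (0, %g) Hz",
                 lo, hi, nyq))
  }
  n <- ncol(epochs$data)
  if (n < 3 * order * 3) stop("epochs too short for the requested filter order")
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  env <- t(apply(epochs$data, 1, function(tr) {
    hilbert_envelope(signal::filtfilt(bf, tr))
  }))
  norm_factor <- switch(normalize,
    session = mean(env),
    trial   = rowMeans(env),
    none    = 1
  )
  divisor <- ifelse(norm_factor == 0, 1, norm_factor)  # silent data stays 0
  env <- env / switch(normalize,
    session = divisor,
    trial   = matrix(divisor, nrow(env), ncol(env)),
    none    = 1
  )
  structure(list(env = env, times = epochs$times, fs = fs,
                 center_freq = center_freq, halfwidth = halfwidth,
                 normalization = normalize, norm_factor = norm_factor),
            class = "envelope_array")
}

#' Burst threshold from envelope statistics
#'
#' `median + k * SD`, pooled over all samples of all trials of one
#' subject-session-region envelope set.
#'
#' @param env an `envelope_array` (or bare matrix).
#' @param k SD multiple above the median (the reference value selected by the
#'   data-driven scan on the motor-learning dataset was 1.4).
#' @return scalar threshold in normalized envelope units.
#' @export
burst_threshold <- function(env, k = 1.4) {
  e <- if (inherits(env, "envelope_array")) env$env else env
  stats::median(e) + k * stats::sd(e)
}

#' Detect beta bursts as suprathreshold envelope runs
#'
#' Binarizes the envelope at `threshold` (strictly above) and extracts
#' maximal contiguous suprathreshold runs per trial. Each run becomes one
#' burst event with onset at its first suprathreshold sample, offset one
#' sample past its last (end-exclusive, matching the half-open window
#' convention), peak at the maximum envelope sample within the run (earliest
#' sample on ties), and duration = offset - onset = run length in ms.
#'
#' @param env an `envelope_array`.
#' @param threshold scalar threshold (> 0), normalized envelope units.
#' @param min_duration_ms minimum run length in ms to count as a burst
#'   (default 0: no minimum).
#' @return list with `events` (tibble: trial, onset_ms, offset_ms, peak_ms,
#'   peak_amp, duration_ms) and `raster` (trials x samples 0/1 matrix with
#'   attribute `threshold`).
#' @export
detect_bursts <- function(env, threshold, min_duration_ms = 0) {
  stopifnot(inherits(env, "envelope_array"), threshold >= 0)
  e <- env$env
  times <- env$times
  dt <- 1000 / env$fs
  supra <- e > threshold
  raster <- supra * 1L
  attr(raster, "threshold") <- threshold
  out <- vector("list", nrow(e))
  for (tr in seq_len(nrow(e))) {
    r <- rle(supra[tr, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & (r$lengths * dt >= min_duration_ms)
    if (!any(keep)) next
    s <- starts[keep]; en <- ends[keep]
    pk <- integer(length(s)); pa <- numeric(length(s))
    for (j in seq_along(s)) {
      seg <- e[tr, s[j]:en[j]]
      i <- which.max(seg)           # earliest sample on ties
      pk[j] <- s[j] + i - 1
      pa[j] <- seg[i]
    }
    out[[tr]] <- tibble::tibble(
      trial = tr,
      onset_ms = times[s],
      offset_ms = times[en] + dt,
      peak_ms = times[pk],
      peak_amp = pa,
      duration_ms = (en - s + 1) * dt
    )
  }
  events <- dplyr::bind_rows(out)
  if (nrow(events) == 0) {
    events <- tibble::tibble(trial = integer(), onset_ms = numeric(),
                             offset_ms = numeric(), peak_ms = numeric(),
                             peak_amp = numeric(), duration_ms = numeric())
  }
  list(events = events, raster = raster)
}

#' Data-driven threshold scan
#'
#' For each candidate SD multiple k, thresholds every envelope set at
#' `median + k * SD` (statistics pooled within the set), counts bursts per
#' trial, and computes the Spearman correlation between per-trial burst count
#' and per-trial mean envelope amplitude. Correlations are averaged across
#' all sets (subjects, sessions, regions); the selected multiple is the
#' argmax of the mean correlation. Sets with zero variance in counts (or
#' amplitudes) have an undefined correlation for that candidate and are
#' excluded from its average; the number excluded is recorded.
#'
#' @param envelopes list of `envelope_array` objects (one per
#'   subject-session-region).
#' @param candidates ascending numeric vector of SD multiples
#'   (default 0.5 to 4 in steps of 0.1).
#' @param min_duration_ms passed to [detect_bursts()].
#' @return list with `candidates`, `mean_rho`, `n_excluded`, `selected`
#'   (class `threshold_scan`).
#' @export
scan_thresholds <- function(envelopes,
                            candidates = seq(0.5, 4.0, by = 0.1),
                            min_duration_ms = 0) {
  stopifnot(length(envelopes) >= 1, length(candidates) >= 1,
            !is.unsorted(candidates))
  for (env in envelopes) {
    if (nrow(env$env) < 2) stop("each envelope set needs >= 2 trials")
  }
  mean_amp <- lapply(envelopes, function(env) rowMeans(env$env))
  stats_per_set <- lapply(envelopes, function(env) {
    c(med = stats::median(env$env), sd = stats::sd(env$env))
  })
  mean_rho <- numeric(length(candidates))
  n_excl <- integer(length(candidates))
  for (ci in seq_along(candidates)) {
    k <- candidates[ci]
    rhos <- rep(NA_real_, length(envelopes))
    for (si in seq_along(envelopes)) {
      th <- stats_per_set[[si]][["med"]] + k * stats_per_set[[si]][["sd"]]
      counts <- count_bursts_per_trial(envelopes[[si]]$env, th,
                                       envelopes[[si]]$fs, min_duration_ms)
      if (stats::sd(counts) == 0 || stats::sd(mean_amp[[si]]) == 0) next
      rhos[si] <- stats::cor(counts, mean_amp[[si]], method = "spearman")
    }
    n_excl[ci] <- sum(is.na(rhos))
    mean_rho[ci] <- if (all(is.na(rhos))) NA_real_ else mean(rhos, na.rm = TRUE)
  }
  if (all(is.na(mean_rho))) stop("no candidate yielded a defined correlation")
  sel <- candidates[which.max(mean_rho)]
  structure(list(candidates = candidates, mean_rho = mean_rho,
                 n_excluded = n_excl, selected = sel),
            class = "threshold_scan")
}

# Suprathreshold run counts per trial (no event table construction).
count_bursts_per_trial <- function(e, threshold, fs, min_duration_ms = 0) {
  dt <- 1000 / fs
  apply(e > threshold, 1, function(row) {
    r <- rle(row)
    sum(r$values & (r$lengths * dt >= min_duration_ms))
  })
}

#' Burst probability (occupancy) per analysis window
#'
#' Mean of the binary burst raster over trials and the samples of each
#' window: the proportion of suprathreshold time points, a value in
#' `[0, 1]`.
#'
#' @param raster trials x samples 0/1 matrix (from [detect_bursts()]).
#' @param times sample times in ms.
#' @param windows a [window_set].
#' @return named numeric vector of per-window occupancy fractions.
#' @export
burst_probability <- function(raster, times, windows = window_set()) {
  vapply(windows, function(w) {
    idx <- window_idx(times, w)
    if (!length(idx)) stop("window outside raster span")
    mean(raster[, idx, drop = FALSE])
  }, numeric(1))
}

#' Post-movement burst timing variability
#'
#' Per trial, smooths the binary burst indicator with a Gaussian kernel and
#' locates the first strict local maximum after 0 ms; trials with no
#' post-zero burst activity are excluded. Returns the across-trial sample
#' SD of these first-peak times (timing variability), their mean (latency),
#' and the per-trial peak times.
#'
#' @param raster trials x samples 0/1 matrix.
#' @param times sample times in ms.
#' @param sigma_smooth_ms Gaussian kernel SD in ms (default 50).
#' @return list: `sd_ms`, `mean_ms`, `peak_times_ms`, `n_retained`.
#' @export
timing_variability <- function(raster, times, sigma_smooth_ms = 50) {
  if (max(times) <= 0) stop("raster does not cover a post-zero span")
  fs <- 1000 / diff(times[1:2])
  sigma <- sigma_smooth_ms * fs / 1000
  peaks <- rep(NA_real_, nrow(raster))
  for (tr in seq_len(nrow(raster))) {
    row <- raster[tr, ]
    if (!any(row == 1)) next
    s <- gauss_smooth(as.numeric(row), sigma)
    pk <- first_peak_after_zero(s, times)
    peaks[tr] <- pk
  }
  pt <- peaks[!is.na(peaks)]
  if (length(pt) < 2) {
    stop("fewer than 2 trials with a post-zero burst peak: SD undefined")
  }
  list(sd_ms = sample_sd(pt), mean_ms = mean(pt), peak_times_ms = peaks,
       n_retained = length(pt))
}

# First strict local maximum of s occurring at time > 0; plateaus resolve to
# their first sample. Returns NA if none.
first_peak_after_zero <- function(s, times) {
  n <- length(s)
  d <- diff(s)
  # collapse flat segments: sign of change, with zeros carried forward/backward
  rising <- d > 0
  falling <- d < 0
  # candidate i (2..n-1): last nonzero diff before i is rising, first nonzero
  # diff at/after i is falling
  last_dir <- integer(n)   # direction arriving at sample i
  dir <- 0L
  for (i in 2:n) {
    if (rising[i - 1]) dir <- 1L else if (falling[i - 1]) dir <- -1L
    last_dir[i] <- dir
  }
  next_dir <- integer(n)   # direction leaving sample i (skipping plateaus)
  dir <- 0L
  for (i in (n - 1):1) {
    if (falling[i]) dir <- -1L else if (rising[i]) dir <- 1L
    next_dir[i] <- dir
  }
  is_peak <- last_dir == 1L & next_dir == -1L
  # plateau: keep first sample of each run of is_peak
  if (any(is_peak)) {
    first_of_run <- is_peak & !c(FALSE, is_peak[-n])
    idx <- which(first_of_run & times > 0)
    if (length(idx)) return(times[idx[1]])
  }
  NA_real_
}

#' Mean burst peak amplitude per window
#'
#' Events are assigned to windows by their peak time; the value is the mean
#' `peak_amp` of events in each window, `NA` where a window holds no event.
#'
#' @param events burst event tibble (from [detect_bursts()]).
#' @param windows a [window_set].
#' @return named numeric vector.
#' @export
burst_amplitude <- function(events, windows = window_set()) {
  window_event_mean(events, windows, "peak_amp")
}

#' Mean burst duration per window (ms)
#'
#' As [burst_amplitude()], with event durations.
#'
#' @inheritParams burst_amplitude
#' @return named numeric vector (ms).
#' @export
burst_duration <- function(events, windows = window_set()) {
  window_event_mean(events, windows, "duration_ms")
}

window_event_mean <- function(events, windows, col) {
  vapply(windows, function(w) {
    v <- events[[col]][events$peak_ms >= w[1] & events$peak_ms < w[2]]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
}

#' Assemble a tidy metrics table
#'
#' Runs the full burst-metric block (probability, timing variability,
#' latency, amplitude, duration) on one envelope set and returns long-format
#' rows keyed by subject/session/group/region/window/metric.
#'
#' @param env an `envelope_array`.
#' @param threshold detection threshold (normalized units).
#' @param windows a [window_set].
#' @param sigma_smooth_ms Gaussian smoothing SD for the timing metric.
#' @param ids named list with subject, session, group, region labels.
#' @return tibble with columns subject, session, group, region, window,
#'   metric, value.
#' @export
assemble_metrics <- function(env, threshold, windows = window_set(),
                             sigma_smooth_ms = 50,
                             ids = list(subject = NA, session = NA,
                                        group = NA, region = NA)) {
  det <- detect_bursts(env, threshold)
  prob <- burst_probability(det$raster, env$times, windows)
  amp <- burst_amplitude(det$events, windows)
  dur <- burst_duration(det$events, windows)
  tv <- tryCatch(timing_variability(det$raster, env$times, sigma_smooth_ms),
                 error = function(e) list(sd_ms = NA_real_, mean_ms = NA_real_))
  rows <- dplyr::bind_rows(
    tibble::tibble(window = names(windows), metric = "probability",
                   value = unname(prob)),
    tibble::tibble(window = names(windows), metric = "amplitude",
                   value = unname(amp)),
    tibble::tibble(window = names(windows), metric = "duration_ms",
                   value = unname(dur)),
    tibble::tibble(window = "postzero", metric = "timing_sd_ms",
                   value = tv$sd_ms),
    tibble::tibble(window = "postzero", metric = "latency_ms",
                   value = tv$mean_ms)
  )
  tibble::tibble(subject = ids$subject %||% NA, session = ids$session %||% NA,
                 group = ids$group %||% NA, region = ids$region %||% NA,
                 rows)
}
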