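# Shared fixtures and small builders used across test files.

# envelope_array built directly from a matrix (bypassing filtering), for
# detector-level tests
env_from_matrix <- function(m, fs = 256, t0 = -2000) {
  times <- t0 + (seq_len(ncol(m)) - 1) * 1000 / fs
  structure(list(env = m, times = times, fs = fs, center_freq = 21,
                 halfwidth = 3, normalization = "none", norm_factor = 1),
            class = "envelope_array")
}

# independent run-length-encoding oracle for burst detection
rle_oracle <- function(env_row, times, threshold, dt) {
  above <- env_row > threshold
  out <- list()
  i <- 1
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      seg <- env_row[i:j]
      pk <- i + which.max(seg) - 1
      out[[length(out) + 1]] <- c(onset = times[i], offset = times[j] + dt,
                                  peak = times[pk], amp = env_row[pk],
                                  dur = (j - i + 1) * dt)
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# loose/fast calibration settings for structural (non-recovery) tests
fast_cal <- function(cfg) {
  calibrate_generator(cfg, n_small = 60, n_large = 120, max_iter = 25,
                      tol = list(occ = 0.04, occ_pre = 0.05, dur = 40,
                                 amp = 0.5, sd = 120, mean = 250))
}

# calibrations are expensive; share them across test files within one run
.cal_cache <- new.env(parent = emptyenv())
cached_calibration <- function(name, cfg) {
  if (is.null(.cal_cache[[name]])) .cal_cache[[name]] <- calibrate_generator(cfg)
  .cal_cache[[name]]
}

# study conditions used by the parameter-recovery acceptance checks
session1_config <- function(seed = 11) {
  burst_gen_config(occupancy = c(baseline = 0.08, movement = 0.06,
                                 postmove = 0.151),
                   duration_ms = c(baseline = NA, movement = NA,
                                   postmove = 134),
                   first_peak_sd_ms = 467, seed = seed)
}
session3_config <- function(seed = 12) {
  burst_gen_config(occupancy = c(baseline = 0.08, movement = 0.06,
                                 postmove = 0.194),
                   duration_ms = c(baseline = NA, movement = NA,
                                   postmove = 150),
                   first_peak_sd_ms = 410, seed = seed)
}
# strong post-movement rebound with movement suppression (ERD/ERS checks)
rebound_config <- function(seed = 2) {
  burst_gen_config(occupancy = c(baseline = 0.08, movement = 0.05,
                                 postmove = 0.24),
                   duration_ms = c(baseline = NA, movement = NA,
                                   postmove = 150),
                   first_peak_mean_ms = 620, first_peak_sd_ms = 280,
                   seed = seed)
}

# minimal synthetic force trial from explicit components
toy_force_trial <- function(target_time = 1500, target_force = 75,
                            peak_time = target_time, peak_force = target_force,
                            fwhm = 120, fs = 256, duration = 3000,
                            right = NULL) {
  time <- seq(0, duration - 1000 / fs, by = 1000 / fs)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  left <- peak_force * exp(-0.5 * ((time - peak_time) / sig)^2)
  if (is.null(right)) right <- rep(target_force, length(time))
  structure(list(time = time, right = right, left = left,
                 target_time = target_time, target_force = target_force,
                 mvc = 300),
            class = "force_trial")
}

gauss_smooth_test <- function(x, sigma) betabursts:::gauss_smooth(x, sigma)
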