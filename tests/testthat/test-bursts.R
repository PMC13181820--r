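test_that("detect_bursts matches the hand-worked run-length example", {
  env <- env_from_matrix(matrix(c(0, 2, 2, 0, 0, 3, 0), 1), fs = 1000)
  det <- detect_bursts(env, threshold = 1)
  expect_equal(nrow(det$events), 2)
  expect_equal(det$events$duration_ms, c(2, 1))
  expect_equal(det$events$peak_amp, c(2, 3))
  expect_equal(det$events$offset_ms - det$events$onset_ms,
               det$events$duration_ms)
  expect_equal(unname(det$raster[1, ]), c(0L, 1L, 1L, 0L, 0L, 1L, 0L))
})

test_that("detect_bursts handles all-sub and all-supra threshold trials", {
  env <- env_from_matrix(rbind(rep(0.1, 50), rep(5, 50)))
  det <- detect_bursts(env, threshold = 1)
  expect_equal(nrow(det$events), 1)
  expect_equal(det$events$trial, 2)
  expect_equal(det$events$duration_ms, 50 * 1000 / 256)
  expect_true(all(det$raster[1, ] == 0))
  expect_true(all(det$raster[2, ] == 1))
})

test_that("burst events and raster agree with an independent RLE oracle on random envelopes", {
  set.seed(41)
  for (rep in 1:25) {
    m <- matrix(abs(stats::rnorm(40 * 120, 1, 0.6)), 40, 120)
    env <- env_from_matrix(m)
    th <- stats::median(m) + 1.4 * stats::sd(m)
    det <- detect_bursts(env, th)
    dt <- 1000 / env$fs
    k <- 0
    for (tr in 1:40) {
      for (ev in rle_oracle(m[tr, ], env$times, th, dt)) {
        k <- k + 1
        expect_equal(det$events$onset_ms[k], ev[["onset"]])
        expect_equal(det$events$offset_ms[k], ev[["offset"]])
        expect_equal(det$events$peak_ms[k], ev[["peak"]])
        expect_equal(det$events$peak_amp[k], ev[["amp"]])
        expect_equal(det$events$duration_ms[k], ev[["dur"]])
      }
    }
    expect_equal(nrow(det$events), k)
    expect_identical(unname(det$raster == 1), m > th)
  }
})

test_that("raising the threshold never increases occupancy or event count", {
  set.seed(7)
  m <- matrix(abs(stats::rnorm(30 * 200, 1, 0.5)), 30, 200)
  env <- env_from_matrix(m)
  ths <- c(0.8, 1.2, 1.6, 2.0)
  counts <- occ <- numeric(length(ths))
  for (i in seq_along(ths)) {
    det <- detect_bursts(env, ths[i])
    counts[i] <- nrow(det$events)
    occ[i] <- mean(det$raster)
  }
  expect_true(all(diff(occ) <= 0))
  expect_true(all(diff(counts) <= 1e-9 + 0))
})

test_that("burst probability equals the direct raster mean and is window-additive", {
  set.seed(5)
  raster <- matrix(rbinom(20 * 1024, 1, 0.2), 20, 1024)
  times <- epoch_times()
  w <- window_set()
  p <- burst_probability(raster, times, w)
  for (nm in names(w)) {
    idx <- which(times >= w[[nm]][1] & times < w[[nm]][2])
    expect_equal(unname(p[nm]), mean(raster[, idx]))
  }
  # occupancy over the union of disjoint windows = duration-weighted mean
  union_idx <- which(times >= -1750 & times < 1250)
  lens <- vapply(w, diff, numeric(1))
  expect_equal(mean(raster[, union_idx]),
               sum(p * lens) / sum(lens))
  expect_equal(unname(burst_probability(matrix(0L, 3, 1024), times, w)),
               c(0, 0, 0))
  expect_equal(unname(burst_probability(matrix(1L, 3, 1024), times, w)),
               c(1, 1, 1))
})

test_that("timing variability recovers hand-computable peak time statistics", {
  times <- epoch_times()
  idx400 <- which.min(abs(times - 400))
  raster <- matrix(0L, 5, length(times))
  raster[, idx400 + (-3:3)] <- 1L     # every trial bursts at +400 ms
  tv <- timing_variability(raster, times)
  expect_equal(tv$sd_ms, 0)
  expect_equal(tv$mean_ms, times[idx400], tolerance = 1e-6)
  expect_equal(tv$n_retained, 5)

  raster2 <- matrix(0L, 2, length(times))
  raster2[1, which.min(abs(times - 300)) + (-3:3)] <- 1L
  raster2[2, which.min(abs(times - 500)) + (-3:3)] <- 1L
  tv2 <- timing_variability(raster2, times)
  expect_equal(tv2$mean_ms, 400, tolerance = 3)
  expect_equal(tv2$sd_ms, 141.42, tolerance = 3)
})

test_that("timing variability excludes burst-free trials and needs two retained", {
  times <- epoch_times()
  raster <- matrix(0L, 3, length(times))
  raster[1, which.min(abs(times - 350)) + (-2:2)] <- 1L
  expect_error(timing_variability(raster, times), "fewer than 2")
  # pre-zero bursts do not count as post-zero peaks
  raster[2, which.min(abs(times + 600)) + (-2:2)] <- 1L
  expect_error(timing_variability(raster, times), "fewer than 2")
})

test_that("window-resolved amplitude and duration match group-by-mean oracles", {
  w <- window_set()
  ev <- tibble::tibble(trial = 1:5,
                       onset_ms = c(-1500, -500, 300, 700, 1300),
                       offset_ms = c(-1400, -400, 450, 900, 1400),
                       peak_ms = c(-1450, -450, 400, 800, 1350),
                       peak_amp = c(2.0, 1.8, 2.3, 2.9, 3.1),
                       duration_ms = c(100, 100, 150, 200, 100))
  amp <- burst_amplitude(ev, w)
  dur <- burst_duration(ev, w)
  expect_equal(unname(amp), c(2.0, 1.8, mean(c(2.3, 2.9))))
  expect_equal(unname(dur), c(100, 100, 175))
  # empty window -> NA
  amp2 <- burst_amplitude(ev[1, ], w)
  expect_true(is.na(amp2[["postmove"]]))
  expect_equal(unname(amp2[["baseline"]]), 2.0)

  set.seed(10)
  ev_r <- tibble::tibble(trial = 1, onset_ms = 0, offset_ms = 1,
                         peak_ms = runif(200, -2000, 2000),
                         peak_amp = runif(200, 1, 4),
                         duration_ms = runif(200, 20, 300))
  amp_r <- burst_amplitude(ev_r, w)
  for (nm in names(w)) {
    sel <- ev_r$peak_ms >= w[[nm]][1] & ev_r$peak_ms < w[[nm]][2]
    expect_equal(unname(amp_r[nm]), mean(ev_r$peak_amp[sel]))
  }
})

test_that("envelope extraction: flat in-band tone, unit session mean, out-of-band rejection", {
  fs <- 256
  times <- epoch_times(c(-2000, 2000), fs)
  tone <- sin(2 * pi * 21 * times / 1000)
  ep <- epoch_array(rbind(tone, tone), times, fs)
  env <- extract_envelope(ep, 21, normalize = "none")
  interior <- seq(round(0.15 * length(times)), round(0.85 * length(times)))
  ripple <- diff(range(env$env[1, interior])) / mean(env$env[1, interior])
  expect_lt(ripple, 0.02)

  env_n <- extract_envelope(ep, 21)
  expect_equal(mean(env_n$env), 1)

  far <- sin(2 * pi * 31 * times / 1000)   # center + 10 Hz
  ep2 <- epoch_array(rbind(tone, far), times, fs)
  env2 <- extract_envelope(ep2, 21, normalize = "none")
  expect_lt(mean(env2$env[2, interior]), 0.1 * mean(env2$env[1, interior]))
})

test_that("envelope band must fit inside (0, Nyquist)", {
  ep <- epoch_array(matrix(stats::rnorm(512), 1), epoch_times(c(-1000, 1000)),
                    256)
  expect_error(extract_envelope(ep, 2), "inside")
  expect_error(extract_envelope(ep, 126), "inside")
})

test_that("threshold scan: single candidate, monotone data, zero-variance exclusion", {
  set.seed(3)
  # envelope set where counts increase strictly with mean amplitude
  rows <- lapply(1:8, function(k) {
    r <- rep(0.5, 400)
    if (k > 1) for (j in seq_len(k - 1)) r[(30 * j):(30 * j + 4)] <- 2 + k / 10
    r
  })
  env <- env_from_matrix(do.call(rbind, rows))
  sc <- scan_thresholds(list(env), candidates = 1.0)
  expect_equal(sc$selected, 1.0)
  sc2 <- scan_thresholds(list(env), candidates = c(0.6, 1.0))
  expect_true(all(abs(sc2$mean_rho[!is.na(sc2$mean_rho)] - 1) < 1e-9))

  # constant envelopes: counts have zero variance -> excluded
  env_const <- env_from_matrix(matrix(1, 3, 50))
  expect_error(scan_thresholds(list(env_const), candidates = c(1, 2)),
               "no candidate")
  # mixed: defined sets still yield a selection, exclusions counted
  sc3 <- scan_thresholds(list(env, env_const), candidates = c(1, 2))
  expect_true(all(sc3$n_excluded >= 1))
  expect_true(sc3$selected %in% c(1, 2))
})

test_that("assemble_metrics produces one tidy row per metric and window", {
  cfg <- burst_gen_config(n_trials = 20, seed = 5)
  cal <- fast_cal(cfg)
  ep <- generate_burst_epochs(cfg, cal)
  env <- extract_envelope(ep, cfg$beta_freq)
  th <- burst_threshold(env, 1.4)
  rows <- assemble_metrics(env, th, ids = list(subject = 1, session = 2,
                                               group = "adaptive",
                                               region = "right_m1"))
  expect_equal(nrow(rows), 3 * 3 + 2)
  expect_setequal(unique(rows$metric),
                  c("probability", "amplitude", "duration_ms",
                    "timing_sd_ms", "latency_ms"))
  expect_true(all(rows$session == 2))
  prob <- rows$value[rows$metric == "probability"]
  expect_true(all(prob >= 0 & prob <= 1))
})
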