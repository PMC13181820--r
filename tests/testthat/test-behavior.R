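test_that("normalize_and_align puts the peak at (0, 1) and is idempotent", {
  time <- seq(0, 3000, by = 4)
  force <- 5 * exp(-0.5 * ((time - 1200) / 60)^2)
  nal <- normalize_and_align(time, force)
  expect_equal(max(nal$force), 1)
  expect_equal(nal$time[which.max(nal$force)], 0)
  expect_equal(nal$peak_time, 1200)
  expect_equal(nal$peak_force, 5)

  again <- normalize_and_align(nal$time, nal$force)
  expect_equal(again$force, nal$force)
  expect_equal(again$time, nal$time)

  expect_error(normalize_and_align(time, numeric(length(time))), "positive")

  # random trace matches an explicit scale-and-shift oracle
  set.seed(1)
  f <- abs(stats::rnorm(length(time))) + 0.1
  nal2 <- normalize_and_align(time, f)
  i <- which.max(f)
  expect_equal(nal2$force, f / f[i])
  expect_equal(nal2$time, time - time[i])
})

test_that("AUC reproduces rectangle and triangle areas and a refined Riemann oracle", {
  time <- seq(-500, 500, by = 1)
  rect <- as.numeric(time >= -100 & time <= 100)
  expect_equal(compute_auc(time, rect, c(-200, 200)), 200, tolerance = 0.01)

  tri <- pmax(0, 1 - abs(time) / 100)
  expect_equal(compute_auc(time, tri, c(-150, 150)), 100, tolerance = 0.01)

  set.seed(2)
  smooth <- gauss_smooth_test(stats::rnorm(length(time)), 20) + 2
  auc <- compute_auc(time, smooth, c(-400, 400))
  fine <- stats::approx(time, smooth, xout = seq(-400, 400, by = 0.05))
  riemann <- sum(fine$y) * 0.05
  expect_equal(auc, riemann, tolerance = abs(riemann) * 0.001)

  expect_error(compute_auc(time, rect, c(600, 700)), "empty")
})

test_that("AUC is shift-invariant and scales linearly with amplitude", {
  time <- seq(0, 1000, by = 2)
  f <- exp(-0.5 * ((time - 400) / 80)^2)
  a1 <- compute_auc(time, f, c(100, 700))
  a2 <- compute_auc(time + 250, f, c(350, 950))
  expect_equal(a1, a2)
  expect_equal(compute_auc(time, 3 * f, c(100, 700)), 3 * a1)
})

test_that("trial evaluation applies the inclusive timing boundary and per-sample oracle", {
  tol <- tolerance_spec(c(70, 80), c(70, 80), timing_window = 125)
  mk <- function(peak_dt) {
    toy_force_trial(target_time = 1500, peak_time = 1500 + peak_dt,
                    target_force = 75)
  }
  # the grid step is ~3.9 ms: stay one sample inside / outside the boundary
  expect_true(evaluate_trial(mk(121), tol)$left_correct)
  expect_false(evaluate_trial(mk(129), tol)$left_correct)

  # constant mid-range right force is fully valid
  tr <- toy_force_trial()
  expect_equal(evaluate_trial(tr, tol)$right_valid_fraction, 1)

  # random right trace: fraction equals a brute-force per-sample check
  set.seed(3)
  tr2 <- toy_force_trial(right = 75 + stats::rnorm(768, sd = 4))
  ev <- evaluate_trial(tr2, tol)
  expect_equal(ev$right_valid_fraction,
               mean(tr2$right >= 70 & tr2$right <= 80))
})

test_that("BPDS is zero iff deviation-free and composes Euclidean components", {
  tr <- toy_force_trial(target_time = 1500, peak_time = 1500)
  r <- compute_bpds(tr)
  expect_equal(r$score, 0)

  # scaled components (3, 4, 0) give exactly 5
  fake <- structure(list(stability_dev = 3, force_dev = 4, timing_dev = 0),
                    class = "bpds_result")
  expect_equal(sqrt(sum(c(3, 4, 0)^2)), 5)
  # and through the real computation: build a trial with known deviations
  tr2 <- toy_force_trial(target_time = 1500, peak_time = 1500,
                         peak_force = 79,                 # force_dev 4 N
                         right = rep(78, 768))            # stability 3 N
  r2 <- compute_bpds(tr2)
  expect_equal(r2$stability_dev, 3, tolerance = 1e-6)
  expect_equal(r2$force_dev, 4, tolerance = 0.05)
  expect_equal(r2$timing_dev, 0, tolerance = 1e-9)
  expect_equal(r2$score, 5, tolerance = 0.05)

  # strictly increasing in each scaled component, others fixed
  base <- compute_bpds(tr2)$score
  tr3 <- toy_force_trial(target_time = 1500, peak_time = 1500,
                         peak_force = 81, right = rep(78, 768))
  expect_gt(compute_bpds(tr3)$score, base)

  # independent recomposition on a synthetic trial with injected errors
  tr4 <- toy_force_trial(target_time = 1500, peak_time = 1578.125,
                         peak_force = 72, right = rep(76.5, 768))
  r4 <- compute_bpds(tr4, scales = c(1.5, 2, 50))
  i <- which.max(tr4$left)
  expect_equal(r4$timing_dev, abs(tr4$time[i] - 1500) / 50)
  expect_equal(r4$force_dev, abs(tr4$left[i] - 75) / 2)
  expect_equal(r4$stability_dev, 1.5 / 1.5, tolerance = 1e-9)
  expect_equal(r4$score, sqrt(sum(c(r4$stability_dev, r4$force_dev,
                                    r4$timing_dev)^2)))
})

test_that("BPDS scaling divides components as declared", {
  tr <- toy_force_trial(target_time = 1500, peak_time = 1500,
                        peak_force = 79, right = rep(78, 768))
  r1 <- compute_bpds(tr, scales = c(1, 1, 1))
  r2 <- compute_bpds(tr, scales = c(3, 2, 10))
  expect_equal(r2$stability_dev, r1$stability_dev / 3)
  expect_equal(r2$force_dev, r1$force_dev / 2)
})

test_that("adaptive rule: below 80 percent leaves tolerance unchanged (idempotent)", {
  rng <- c(70, 80)
  out <- update_tolerance(c(71, 79, 85), 75, accuracy = 0.79, rng)
  expect_identical(out, rng)
  out2 <- update_tolerance(c(71, 79, 85), 75, accuracy = 0.79, out)
  expect_identical(out2, rng)
})

test_that("adaptive rule narrows to the 70 percent closest responses (sort oracle)", {
  # 10 responses at distances 1..10 from the target
  target <- 100
  resp <- target + c(1, -2, 3, -4, 5, -6, 7, -8, 9, -10)
  out <- update_tolerance(resp, target, accuracy = 0.9, c(85, 115))
  kept <- resp[order(abs(resp - target))][1:7]
  expect_equal(out, range(kept))

  set.seed(9)
  for (i in 1:20) {
    r <- stats::rnorm(25, 50, 8)
    rng <- c(30, 70)
    out <- update_tolerance(r, 50, accuracy = 0.85, rng)
    n_keep <- ceiling(0.7 * length(r))
    oracle <- range(r[order(abs(r - 50))][seq_len(n_keep)])
    oracle <- c(max(oracle[1], rng[1]), min(oracle[2], rng[2]))
    expect_equal(out, oracle)
    # narrowed range never widens
    expect_gte(out[1], rng[1])
    expect_lte(out[2], rng[2])
  }
})

test_that("adaptive rule: degenerate responses widen to epsilon; empty responses error", {
  out <- update_tolerance(rep(75, 10), 75, accuracy = 0.95, c(70, 80))
  expect_gt(diff(out), 0)
  expect_equal(diff(out), 2 * 0.005 * 75, tolerance = 1e-9)
  expect_error(update_tolerance(numeric(0), 75, accuracy = 0.9, c(70, 80)),
               "no responses")
})

test_that("behavior summary reduces to the trial value for one trial and matches hand stats", {
  tol <- tolerance_spec(c(70, 80), c(70, 80))
  tr1 <- toy_force_trial(target_time = 1500, peak_time = 1500)
  s1 <- summarize_behavior(list(tr1), tol)
  expect_equal(s1$mean[s1$measure == "bpds"], compute_bpds(tr1)$score)
  expect_equal(s1$mean[s1$measure == "right_correct_pct"], 100)
  expect_equal(s1$mean[s1$measure == "left_correct_pct"], 100)

  tr2 <- toy_force_trial(target_time = 1500, peak_time = 1700)  # late pulse
  s2 <- summarize_behavior(list(tr1, tr2), tol)
  b1 <- compute_bpds(tr1)$score; b2 <- compute_bpds(tr2)$score
  expect_equal(s2$mean[s2$measure == "bpds"], mean(c(b1, b2)))
  expect_equal(s2$sd[s2$measure == "bpds"], stats::sd(c(b1, b2)))
  expect_equal(s2$mean[s2$measure == "left_correct_pct"], 50)
})
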