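#' Tolerance specification for the bimanual task
#'
#' Allowed force ranges per hand and the timing window for the left-hand
#' ballistic pulse. Narrower ranges mean higher difficulty.
#'
#' @param right_range N pair (low, high) for the sustained right-hand hold.
#' @param left_range N pair for the left-hand peak force.
#' @param timing_window ms; the pulse is on time if its peak is within
#'   +/- this of the target center (boundary inclusive).
#' @return a `tolerance_spec` object.
#' @export
tolerance_spec <- function(right_range, left_range, timing_window = 125) {
  stopifnot(length(right_range) == 2, right_range[1] <= right_range[2],
            length(left_range) == 2, left_range[1] <= left_range[2],
            timing_window > 0)
  structure(list(right_range = right_range, left_range = left_range,
                 timing_window = timing_window),
            class = "tolerance_spec")
}

#' Peak-normalize and time-align a left-hand force trace
#'
#' Scales the trace to a peak of 1 and shifts the time axis so the peak sits
#' at 0 ms. Idempotent; ties in the maximum resolve to the earliest sample.
#'
#' @param time ms grid.
#' @param force force trace (N), strictly positive somewhere.
#' @return list: `time` (shifted), `force` (peak 1), `peak_time`
#'   (original ms), `peak_force` (original N).
#' @export
normalize_and_align <- function(time, force) {
  stopifnot(length(time) == length(force))
  if (all(force <= 0)) stop("force trace has no positive maximum")
  i <- which.max(force)
  list(time = time - time[i], force = force / force[i],
       peak_time = time[i], peak_force = force[i])
}

#' Area under a force trace over a window
#'
#' Trapezoidal integral of the trace over `[window[1], window[2]]` ms. For a
#' peak-normalized trace the unit is ms.
#'
#' @param time ms grid.
#' @param force trace values.
#' @param window ms pair within the trace support.
#' @return scalar area.
#' @export
compute_auc <- function(time, force, window) {
  stopifnot(length(time) == length(force), length(window) == 2)
  idx <- which(time >= window[1] & time <= window[2])
  if (length(idx) < 2) stop("empty or degenerate integration window")
  pracma::trapz(time[idx], force[idx])
}

#' Evaluate one trial against the tolerance criteria
#'
#' The right hand is scored by the fraction of trajectory samples inside its
#' force range; the left hand is correct if the pulse peak force falls in
#' range and the peak occurs within the timing window of the target center
#' (inclusive).
#'
#' @param trial a `force_trial` (see [generate_force_trials()]) or any list
#'   with `time`, `right`, `left`, `target_time`.
#' @param tol a [tolerance_spec].
#' @return list: `right_valid_fraction`, `left_correct`, `left_peak_time`,
#'   `left_peak_force`.
#' @export
evaluate_trial <- function(trial, tol) {
  stopifnot(inherits(tol, "tolerance_spec"))
  rv <- mean(trial$right >= tol$right_range[1] &
               trial$right <= tol$right_range[2])
  i <- which.max(trial$left)
  pk_t <- trial$time[i]; pk_f <- trial$left[i]
  left_ok <- pk_f >= tol$left_range[1] && pk_f <= tol$left_range[2] &&
    abs(pk_t - trial$target_time) <= tol$timing_window
  list(right_valid_fraction = rv, left_correct = left_ok,
       left_peak_time = pk_t, left_peak_force = pk_f)
}

#' Bimanual Performance Deviation Score (BPDS)
#'
#' Combines three deviations into one Euclidean score: (1) right-hand force
#' stability, the RMSE of the right force against its target over the 226 ms
#' window ending at the left-hand peak (window `[peak - 226, peak)`);
#' (2) the absolute left peak-force deviation; (3) the absolute timing
#' error. Each component is divided by its scale factor before combination,
#' making newtons and milliseconds commensurable; scale factors are reported
#' back so alternative scalings stay explicit. Lower scores are better; a
#' deviation-free trial scores exactly 0.
#'
#' @param trial a `force_trial`-like list (`time`, `right`, `left`,
#'   `target_time`, `target_force`).
#' @param scales length-3 positive numeric: scale factors for the stability
#'   (N), force (N) and timing (ms) components, e.g. baseline-session SDs.
#' @param stability_window_ms length of the pre-peak stability window (226).
#' @return a `bpds_result`: `stability_dev`, `force_dev`, `timing_dev`
#'   (scaled), `scale_factors`, `score`.
#' @export
compute_bpds <- function(trial, scales = c(1, 1, 1),
                         stability_window_ms = 226) {
  stopifnot(length(scales) == 3, all(scales > 0))
  if (all(trial$left <= 0)) stop("no detectable left-hand peak")
  i <- which.max(trial$left)
  pk_t <- trial$time[i]
  w0 <- pk_t - stability_window_ms
  if (w0 < trial$time[1]) stop("stability window extends before trial start")
  idx <- which(trial$time >= w0 & trial$time < pk_t)
  stability <- sqrt(mean((trial$right[idx] - trial$target_force)^2))
  force_dev <- abs(trial$left[i] - trial$target_force)
  timing_dev <- abs(pk_t - trial$target_time)
  comps <- c(stability, force_dev, timing_dev) / scales
  structure(list(stability_dev = comps[1], force_dev = comps[2],
                 timing_dev = comps[3], scale_factors = scales,
                 score = sqrt(sum(comps^2))),
            class = "bpds_result")
}

#' Adaptive tolerance update rule
#'
#' Implements the difficulty-scaling rule of adaptive training: if accuracy
#' for a hand reaches 80%, its tolerance range for the next session is
#' narrowed to the smallest interval containing the 70% of responses closest
#' to the target; below 80% the range is unchanged. The narrowed range never
#' widens beyond the current one, and a degenerate range (all kept responses
#' identical) is widened to a minimal width.
#'
#' @param responses realized values (force in N, or timing in ms) from the
#'   previous session.
#' @param target target value the distances are measured from.
#' @param accuracy fraction correct in the previous session, in `[0, 1]`.
#' @param range current length-2 tolerance range.
#' @param epsilon minimal half-width for a degenerate narrowed range
#'   (default 0.5 percent of the target magnitude, floor 1e-6).
#' @return updated length-2 range.
#' @export
update_tolerance <- function(responses, target, accuracy, range,
                             epsilon = max(0.005 * abs(target), 1e-6)) {
  stopifnot(length(range) == 2, range[1] <= range[2],
            accuracy >= 0, accuracy <= 1)
  if (accuracy < 0.80) return(range)
  if (!length(responses)) {
    stop("accuracy >= 80% but no responses to narrow the range from")
  }
  n_keep <- ceiling(0.7 * length(responses))
  kept <- responses[order(abs(responses - target))][seq_len(n_keep)]
  new_range <- range(kept)
  if (diff(new_range) == 0) new_range <- new_range + c(-1, 1) * epsilon
  # narrowing only: never extend beyond the current range
  c(max(new_range[1], range[1]), min(new_range[2], range[2]))
}

#' Session-level behavior summary
#'
#' Per-session mean and SD of BPDS and AUC plus percent-correct per hand,
#' in tidy long format.
#'
#' @param trials list of `force_trial` objects for one session.
#' @param tol a [tolerance_spec].
#' @param scales BPDS scale factors (see [compute_bpds()]).
#' @param auc_window ms window for the AUC of the peak-normalized left
#'   trace (relative to the peak at 0).
#' @param session session label attached to the rows.
#' @return tibble: session, measure, mean, sd, n.
#' @export
summarize_behavior <- function(trials, tol, scales = c(1, 1, 1),
                               auc_window = c(-500, 500), session = 1) {
  stopifnot(length(trials) >= 1)
  bpds <- vapply(trials, function(tr) compute_bpds(tr, scales)$score,
                 numeric(1))
  auc <- vapply(trials, function(tr) {
    nal <- normalize_and_align(tr$time, tr$left)
    w <- c(max(auc_window[1], nal$time[1]),
           min(auc_window[2], nal$time[length(nal$time)]))
    compute_auc(nal$time, nal$force, w)
  }, numeric(1))
  ev <- lapply(trials, evaluate_trial, tol = tol)
  right_pc <- 100 * mean(vapply(ev, function(e)
    e$right_valid_fraction == 1, logical(1)))
  left_pc <- 100 * mean(vapply(ev, function(e) e$left_correct, logical(1)))
  tibble::tibble(
    session = session,
    measure = c("bpds", "auc_ms", "right_correct_pct", "left_correct_pct"),
    mean = c(mean(bpds), mean(auc), right_pc, left_pc),
    sd = c(sample_sd(bpds), sample_sd(auc), NA, NA),
    n = length(trials))
}
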