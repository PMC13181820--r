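#' Write an epoch array to a text container
#'
#' Stores the trials x samples matrix as TSV together with a YAML metadata
#' sidecar (time axis, sampling rate, subject/session/region/seed
#' attributes), as `<stem>.tsv` and `<stem>.yaml`.
#'
#' @param epochs an [epoch_array].
#' @param stem output path without extension.
#' @return the stem, invisibly.
#' @export
write_epochs <- function(epochs, stem) {
  stopifnot(inherits(epochs, "epoch_array"))
  utils::write.table(epochs$data, paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- c(list(fs = epochs$fs, t_start = epochs$times[1],
                 t_step = 1000 / epochs$fs,
                 n_trials = nrow(epochs$data),
                 n_samples = ncol(epochs$data)),
            epochs$meta[vapply(epochs$meta, function(x)
              is.atomic(x) && length(x) == 1, logical(1))])
  yaml::write_yaml(meta, paste0(stem, ".yaml"))
  invisible(stem)
}

#' Load an epoch array from a text container
#'
#' Reads the `<stem>.tsv` / `<stem>.yaml` pair written by [write_epochs()],
#' validating the schema: both files present, required metadata fields, and
#' matrix dimensions consistent with the metadata.
#'
#' @param stem path without extension.
#' @return an [epoch_array].
#' @export
load_epochs <- function(stem) {
  tsv <- paste0(stem, ".tsv"); yml <- paste0(stem, ".yaml")
  if (!file.exists(tsv)) stop("schema error: missing data file ", tsv)
  if (!file.exists(yml)) stop("schema error: missing metadata file ", yml)
  meta <- yaml::read_yaml(yml)
  req <- c("fs", "t_start", "t_step", "n_trials", "n_samples")
  miss <- setdiff(req, names(meta))
  if (length(miss)) {
    stop("schema error: metadata lacks field(s) ", paste(miss, collapse = ", "))
  }
  if (abs(meta$t_step - 1000 / meta$fs) > 1e-6) {
    stop("schema error: non-uniform or inconsistent sampling (t_step vs fs)")
  }
  data <- as.matrix(utils::read.table(tsv, sep = "\t"))
  dimnames(data) <- NULL
  if (nrow(data) != meta$n_trials || ncol(data) != meta$n_samples) {
    stop(sprintf("schema error: data is %d x %d but metadata says %d x %d",
                 nrow(data), ncol(data), meta$n_trials, meta$n_samples))
  }
  times <- meta$t_start + (seq_len(meta$n_samples) - 1) * meta$t_step
  extra <- meta[setdiff(names(meta), req)]
  epoch_array(data, times, meta$fs, meta = extra)
}

#' Plot-ready burst raster export
#'
#' One row per burst tick (trial, peak time), the data behind a raster plot
#' of burst timing across trials.
#'
#' @param events burst event tibble (from [detect_bursts()]).
#' @param path optional TSV path; when given the table is also written.
#' @return tibble with columns `trial`, `peak_ms`.
#' @export
export_raster_plot_data <- function(events, path = NULL) {
  out <- tibble::tibble(trial = events$trial, peak_ms = events$peak_ms)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  out
}

#' Pipeline configuration
#'
#' Bundles every knob of an end-to-end synthetic-study run. Fully
#' serializable; [run_pipeline()] writes the resolved configuration next to
#' its outputs so any run can be regenerated.
#'
#' @param study a [study_config].
#' @param wavelet a [wavelet_spec].
#' @param windows a [window_set].
#' @param threshold_sd fixed SD multiple for detection; `NULL` runs the
#'   data-driven scan instead.
#' @param candidates candidate SD multiples for the scan.
#' @param sigma_smooth_ms Gaussian smoothing for the timing metric.
#' @param cal_args list of extra arguments for [calibrate_generator()].
#' @param seed master seed of the run.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(study = study_config(n_subjects = 2,
                                                 sessions = 1,
                                                 regions = "right_m1"),
                            wavelet = wavelet_spec(),
                            windows = window_set(),
                            threshold_sd = 1.4,
                            candidates = seq(0.5, 4, by = 0.1),
                            sigma_smooth_ms = 50,
                            cal_args = list(),
                            seed = 1) {
  structure(list(study = study, wavelet = wavelet, windows = windows,
                 threshold_sd = threshold_sd, candidates = candidates,
                 sigma_smooth_ms = sigma_smooth_ms, cal_args = cal_args,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full synthetic-study pipeline
#'
#' Generates the study, extracts envelopes at each subject's peak beta
#' frequency estimate (reference session), selects the detection threshold
#' (fixed SD multiple or data-driven scan), detects bursts, assembles the
#' long metrics table, and writes all artifacts plus a provenance manifest
#' under `out_dir`. Deterministic under the config's seeds.
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @param verbose print stage progress.
#' @return list: `metrics` (tibble), `manifest`, `threshold`, `scan`
#'   (or NULL), `events` (named list per dataset).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)

  say("stage 1/4: synthetic study generation")
  study <- tryCatch(generate_study(config$study, cal_args = config$cal_args),
                    error = function(e) stop("stage synthgen: ",
                                             conditionMessage(e)))

  say("stage 2/4: envelope extraction")
  base <- config$study$base
  envs <- tryCatch(
    lapply(study$epochs, function(ep)
      extract_envelope(ep, base$beta_freq, base$halfwidth)),
    error = function(e) stop("stage envelope: ", conditionMessage(e)))

  say("stage 3/4: threshold selection and burst detection")
  scan <- NULL
  k <- config$threshold_sd
  if (is.null(k)) {
    scan <- tryCatch(scan_thresholds(envs, config$candidates),
                     error = function(e) stop("stage scan: ",
                                              conditionMessage(e)))
    k <- scan$selected
  }

  say("stage 4/4: burst metrics")
  rows <- vector("list", length(envs))
  events <- vector("list", length(envs))
  for (i in seq_along(envs)) {
    th <- burst_threshold(envs[[i]], k)
    meta <- study$epochs[[i]]$meta
    rows[[i]] <- assemble_metrics(
      envs[[i]], th, config$windows, config$sigma_smooth_ms,
      ids = list(subject = meta$subject, session = meta$session,
                 group = meta$group, region = meta$region))
    events[[i]] <- detect_bursts(envs[[i]], th)$events
  }
  names(events) <- names(study$epochs)
  metrics <- dplyr::bind_rows(rows)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(study$manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    yaml::write_yaml(list(threshold_sd = k, seed = config$seed,
                          sigma_smooth_ms = config$sigma_smooth_ms,
                          windows = lapply(config$windows, as.numeric),
                          master_seed = config$study$master_seed),
                     file.path(out_dir, "config_resolved.yaml"))
  }
  list(metrics = metrics, manifest = study$manifest, threshold = k,
       scan = scan, events = events)
}
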