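#' Default analysis configuration
#'
#' Nested list mirroring the YAML configuration schema: `psd` (epoch_s 30,
#' bin_hz 2), `bands` (named `[low, high]` pairs), `artifact` (eeg_mV 0.2,
#' emg_mV 1), `spikes` (detection/chaining rules), `sleep` (membership
#' anchors), `mea` (burst detection parameters, activity-scan and
#' network-assay geometry).
#'
#' @return a named list (schema version in `$config_version`).
#' @export
default_config <- function() {
  list(
    config_version = 1,
    psd = list(epoch_s = 30, bin_hz = 2, band_epoch_s = 10),
    bands = list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
                 beta = c(12, 30), gamma = c(30, 50)),
    artifact = list(eeg_mV = 0.2, emg_mV = 1),
    spikes = list(threshold_uV = 200, min_spike_dur_ms = 1,
                  max_spike_dur_ms = 200, isi_min_s = 0.05, isi_max_s = 0.5,
                  min_spikes_per_train = 3, min_train_time_s = 1),
    sleep = list(delta_paradoxical_wake = 0.5, delta_sws = 1,
                 theta_wake_sws = 1.3, theta_paradoxical = 3,
                 emg_paradoxical_sws = 1, emg_wake = 2.4,
                 activity_active_wake = 0.1, emg_active_wake_factor = 1.5),
    mea = list(bin_width_s = 0.01, gaussian_sigma_s = 0.1, threshold_k = 3,
               min_spikes = 50, min_peak_separation_s = 0.2,
               boundary_fraction = 0.1, scan_duration_s = 30,
               network_electrodes = 1024, assay_duration_s = 300)
  )
}

#' Load a YAML configuration
#'
#' Reads a YAML file and merges it over [default_config()]; keys absent
#' from the file keep their defaults.
#'
#' @param path path to a YAML file (NULL returns the defaults).
#' @return a configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_in <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
        merge_in(base[[k]], over[[k]])
      } else {
        over[[k]]
      }
    }
    base
  }
  merge_in(cfg, user)
}

config_bands <- function(cfg) {
  do.call(eeg_bands, lapply(cfg$bands, as.numeric))
}

config_spike_params <- function(cfg) do.call(spike_params, cfg$spikes)

config_anchors <- function(cfg) do.call(stage_anchors, cfg$sleep)

config_artifact <- function(cfg) {
  artifact_params(eeg_limit_mV = cfg$artifact$eeg_mV,
                  emg_limit_mV = cfg$artifact$emg_mV)
}

config_burst_params <- function(cfg) {
  burst_params(bin_width = cfg$mea$bin_width_s,
               gaussian_sigma = cfg$mea$gaussian_sigma_s,
               threshold_k = cfg$mea$threshold_k,
               min_spikes = cfg$mea$min_spikes,
               min_peak_separation = cfg$mea$min_peak_separation_s,
               boundary_fraction = cfg$mea$boundary_fraction)
}

#' Run the full EEG analysis pipeline
#'
#' End-to-end telemetry analysis of one recording: artifact flagging,
#' recording-averaged (binned) power spectrum, per-band mean powers over
#' 10-s epochs, spike and spike-train detection with summary, and (when
#' EMG and activity channels are present) sleep staging with stage
#' percentages. The run is deterministic: the same input and configuration
#' reproduce the report exactly.
#'
#' @param input a [telemetry_recording()] or path to a recording CSV
#'   (see [read_recording_csv()]).
#' @param config configuration list from [default_config()] /
#'   [load_config()].
#' @return a list of class `eeg_report`: `meta`, `psd` (data frame),
#'   `band_powers` (data frame), `spike_summary`, `spikes`, `trains`,
#'   and, when stageable, `hypnogram` and `sleep_summary`.
#' @export
run_eeg_pipeline <- function(input, config = default_config()) {
  recording <- if (inherits(input, "telemetry_recording")) input
  else read_recording_csv(input)
  bands <- config_bands(config)
  art <- config_artifact(config)
  sp_par <- config_spike_params(config)

  psd <- average_psd(recording, epoch_length = config$psd$epoch_s,
                     bin_hz = config$psd$bin_hz, artifact = art)
  bp <- recording_band_powers(recording, bands,
                              epoch_length = config$psd$band_epoch_s,
                              artifact = art)
  eeg <- recording$channels$EEG
  spikes <- detect_spikes(eeg$samples, eeg$sampling_rate, sp_par)
  trains <- group_spike_trains(spikes, sp_par)
  report <- list(
    meta = list(duration_s = recording$duration,
                eeg_sampling_rate = eeg$sampling_rate,
                n_band_epochs = attr(bp, "n_epochs"),
                config_version = config$config_version),
    psd = data.frame(frequency_hz = psd$frequency, power = psd$power),
    band_powers = as.data.frame(bp),
    spikes = spikes, trains = trains,
    spike_summary = summarize_spiking(trains, spikes, recording$duration)
  )
  if (!is.null(recording$channels$EMG) && !is.null(recording$channels$ACTIVITY)) {
    hyp <- stage_recording(recording, anchors = config_anchors(config),
                           bands = bands, artifact = art)
    report$hypnogram <- as.data.frame(hyp)
    report$sleep_summary <- summarize_hypnogram(hyp)
  }
  structure(report, class = "eeg_report")
}

#' Read an MEA spike table
#'
#' CSV/TSV with columns `electrode_id` and `spike_time_s`; the delimiter is
#' inferred from the extension.
#'
#' @param path path to the spike table.
#' @param duration_s recording duration (defaults to the last spike time).
#' @param n_electrodes_total chip capacity (default 26400).
#' @return a [spike_raster()].
#' @export
read_spike_table <- function(path, duration_s = NULL,
                             n_electrodes_total = 26400) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.csv(path, sep = sep)
  if (!all(c("electrode_id", "spike_time_s") %in% names(df))) {
    stop("spike table must contain electrode_id and spike_time_s")
  }
  if (is.null(duration_s)) {
    duration_s <- if (nrow(df)) max(df$spike_time_s) else 0
  }
  spike_raster(df$electrode_id, df$spike_time_s, duration_s,
               n_electrodes_total = n_electrodes_total)
}

#' Run the MEA network-burst pipeline
#'
#' For a full-chip activity scan (more electrodes than the network-assay
#' subset), summarizes per-electrode rates and selects the
#' highest-firing subset; then computes the Gaussian-smoothed population
#' rate, detects network bursts, and reports burst metrics. An empty spike
#' table yields a zero-metric report with a warning.
#'
#' @param input a [spike_raster()] or path to a spike table CSV/TSV.
#' @param config configuration list.
#' @param metadata optional list carried into the report (e.g. `div`,
#'   `genotype`).
#' @return a list of class `mea_report`: `meta`, optionally
#'   `activity_scan` and `selected_electrodes`, `bursts` (data frame),
#'   `metrics`.
#' @export
run_mea_pipeline <- function(input, config = default_config(),
                             metadata = list()) {
  raster <- if (inherits(input, "spike_raster")) input
  else read_spike_table(input)
  report <- list(meta = c(list(duration_s = raster$duration,
                               n_events = nrow(raster$events),
                               config_version = config$config_version),
                          metadata))
  if (nrow(raster$events) == 0) {
    warning("empty spike table; zero-metric report")
    report$bursts <- detect_network_bursts(
      structure(list(time = numeric(0), rate = numeric(0),
                     bin_width = config$mea$bin_width_s,
                     params = config_burst_params(config)),
                class = "population_rate"),
      raster, config_burst_params(config))
    report$metrics <- burst_metrics(report$bursts, raster$duration)
    return(structure(report, class = "mea_report"))
  }
  n_sel <- config$mea$network_electrodes
  if (raster$n_electrodes_total > n_sel) {
    scan <- summarize_activity_scan(raster, config$mea$scan_duration_s)
    sel <- select_top_electrodes(scan, n_sel)
    report$activity_scan <- scan
    report$selected_electrodes <- sel
    keep <- raster$events$electrode_id %in% sel
    raster <- spike_raster(raster$events$electrode_id[keep],
                           raster$events$spike_time[keep],
                           raster$duration,
                           n_electrodes_total = raster$n_electrodes_total,
                           selected_electrodes = sel)
  }
  bp <- config_burst_params(config)
  rate <- population_rate(raster, bp)
  report$bursts <- detect_network_bursts(rate, raster, bp)
  report$metrics <- burst_metrics(report$bursts, raster$duration)
  structure(report, class = "mea_report")
}

#' Write a report to disk
#'
#' Emits one JSON file with the scalar summaries plus tidy CSV tables
#' (PSD, band powers, spikes, trains, hypnogram or bursts as applicable).
#'
#' @param report an `eeg_report` or `mea_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put_csv <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  scalars <- list(meta = report$meta)
  if (inherits(report, "eeg_report")) {
    put_csv(report$psd, "psd")
    put_csv(report$band_powers, "band_powers")
    put_csv(report$spikes, "spikes")
    put_csv(report$trains, "trains")
    scalars$spike_summary <- unclass(report$spike_summary)
    if (!is.null(report$hypnogram)) {
      put_csv(report$hypnogram, "hypnogram")
      scalars$sleep_summary <- list(
        percent = as.list(report$sleep_summary$percent),
        scored_hours = report$sleep_summary$scored_hours,
        artifact_fraction = report$sleep_summary$artifact_fraction)
    }
  } else {
    put_csv(report$bursts, "bursts")
    if (!is.null(report$activity_scan)) put_csv(report$activity_scan, "activity_scan")
    scalars$metrics <- unclass(report$metrics)
  }
  p <- file.path(dir, "report.json")
  jsonlite::write_json(scalars, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(paths, p))
}
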