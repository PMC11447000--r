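#' Construct a multichannel telemetry recording
#'
#' Container for a wireless-telemetry session: a cortical EEG channel, an
#' optional nuchal EMG channel (both in microvolts) and an optional
#' accelerometer-derived activity channel in arbitrary units. Channels may
#' have different sampling rates; telemetry hardware typically samples
#' biopotentials at 500 Hz and activity at 200 Hz.
#'
#' @param eeg numeric vector of EEG samples (microvolts).
#' @param emg optional numeric vector of EMG samples (microvolts).
#' @param activity optional numeric vector of activity samples (arbitrary
#'   units, same scale the sleep scorer's 0.1 active-wake threshold assumes).
#' @param fs_eeg,fs_emg,fs_activity sampling rates in Hz.
#' @param start_time recording start offset in seconds.
#' @return an object of class `telemetry_recording` with elements
#'   `channels` (named list of `label`, `samples`, `sampling_rate`),
#'   `start_time` and `duration` (seconds).
#' @examples
#' rec <- telemetry_recording(eeg = sin(2 * pi * 2 * seq(0, 30, by = 1/500)))
#' rec$duration
#' @export
telemetry_recording <- function(eeg, emg = NULL, activity = NULL,
                                fs_eeg = 500, fs_emg = 500, fs_activity = 200,
                                start_time = 0) {
  mk <- function(label, samples, fs) {
    stopifnot(is.numeric(samples), fs > 0)
    list(label = label, samples = as.numeric(samples), sampling_rate = fs)
  }
  channels <- list(EEG = mk("EEG", eeg, fs_eeg))
  if (!is.null(emg)) channels$EMG <- mk("EMG", emg, fs_emg)
  if (!is.null(activity)) channels$ACTIVITY <- mk("ACTIVITY", activity, fs_activity)

  durations <- vapply(channels, function(ch) length(ch$samples) / ch$sampling_rate,
                      numeric(1))
  duration <- durations[["EEG"]]
  # channels must agree on duration to within one sample of the slowest rate
  slack <- max(vapply(channels, function(ch) 1 / ch$sampling_rate, numeric(1)))
  if (any(abs(durations - duration) > slack)) {
    stop("channel durations disagree: ",
         paste(sprintf("%s=%.3fs", names(durations), durations), collapse = ", "))
  }
  structure(list(channels = channels, start_time = start_time,
                 duration = duration),
            class = "telemetry_recording")
}

#' @export
print.telemetry_recording <- function(x, ...) {
  cat(sprintf("<telemetry_recording> %.1f s, channels: %s\n", x$duration,
              paste(sprintf("%s @ %g Hz", names(x$channels),
                            vapply(x$channels, `[[`, numeric(1), "sampling_rate")),
                    collapse = ", ")))
  invisible(x)
}

#' Read a recording from a plain-text CSV export
#'
#' Expects columns `time_s`, `eeg_uV`, and optionally `emg_uV` and
#' `activity`, all on a common time base; the sampling rate is inferred from
#' the time column.
#'
#' @param path path to the CSV file.
#' @return a [telemetry_recording()].
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "eeg_uV") %in% names(df))) {
    stop("CSV must contain columns time_s and eeg_uV")
  }
  dt <- diff(df$time_s)
  if (length(dt) < 1 || any(dt <= 0)) stop("time_s must be strictly increasing")
  fs <- round(1 / stats::median(dt), 3)  # absorb text round-trip jitter
  telemetry_recording(
    eeg = df$eeg_uV,
    emg = if ("emg_uV" %in% names(df)) df$emg_uV,
    activity = if ("activity" %in% names(df)) df$activity,
    fs_eeg = fs, fs_emg = fs, fs_activity = fs,
    start_time = df$time_s[1]
  )
}

#' Write a recording to the CSV interchange format
#'
#' All channels are emitted on the EEG time base; slower channels are
#' sample-held. Intended for small fixtures and round-tripping, not bulk
#' storage.
#'
#' @param recording a [telemetry_recording()].
#' @param path output path.
#' @export
write_recording_csv <- function(recording, path) {
  eeg <- recording$channels$EEG
  n <- length(eeg$samples)
  t <- recording$start_time + (seq_len(n) - 1) / eeg$sampling_rate
  df <- data.frame(time_s = t, eeg_uV = eeg$samples)
  hold <- function(ch) {
    idx <- pmin(length(ch$samples),
                floor((t - recording$start_time) * ch$sampling_rate + 1e-6) + 1)
    ch$samples[idx]
  }
  if (!is.null(recording$channels$EMG)) df$emg_uV <- hold(recording$channels$EMG)
  if (!is.null(recording$channels$ACTIVITY)) df$activity <- hold(recording$channels$ACTIVITY)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

channel_or_stop <- function(recording, label) {
  ch <- recording$channels[[label]]
  if (is.null(ch)) stop("recording has no ", label, " channel")
  ch
}

# sample index range of epoch [start, start + len) in a channel (half-open:
# the sample landing exactly on the upper edge belongs to the next epoch)
epoch_sample_range <- function(start, len, fs, n_total) {
  i0 <- floor(start * fs + 0.5) + 1L
  i1 <- floor((start + len) * fs + 0.5)
  c(max(1L, i0), min(n_total, i1))
}

epoch_samples <- function(ch, start, len) {
  r <- epoch_sample_range(start, len, ch$sampling_rate, length(ch$samples))
  ch$samples[r[1]:r[2]]
}

#' Divide a recording into contiguous fixed-length epochs
#'
#' Epochs are half-open intervals `[t, t + L)`; a trailing partial epoch is
#' discarded. The returned grid carries an artifact mask, initially all
#' `FALSE`, which downstream averaging and sleep scoring honour.
#'
#' @param recording a [telemetry_recording()].
#' @param epoch_length epoch length in seconds (30 for PSD epochs, 10 for
#'   band averaging and sleep scoring).
#' @return an object of class `epoch_grid` with `epoch_starts` (seconds,
#'   relative to recording start), `epoch_length` and `artifact` mask.
#' @export
segment_epochs <- function(recording, epoch_length) {
  stopifnot(inherits(recording, "telemetry_recording"), epoch_length > 0)
  n <- floor(recording$duration / epoch_length + 1e-9)
  if (n < 1) {
    stop("recording too short: ", recording$duration, " s is less than one ",
         epoch_length, " s epoch")
  }
  structure(list(epoch_starts = (seq_len(n) - 1) * epoch_length,
                 epoch_length = epoch_length,
                 artifact = rep(FALSE, n)),
            class = "epoch_grid")
}

#' @export
print.epoch_grid <- function(x, ...) {
  cat(sprintf("<epoch_grid> %d x %g s epochs, %d flagged artifact\n",
              length(x$epoch_starts), x$epoch_length, sum(x$artifact)))
  invisible(x)
}

#' Artifact amplitude limits
#'
#' Telemetry signal is treated as artifact when the rectified, mean-removed
#' trace reaches 0.2 mV on EEG or 1 mV on EMG within an epoch.
#'
#' @param eeg_limit_mV,emg_limit_mV amplitude limits in millivolts.
#' @return a list of class `artifact_params` (limits stored in microvolts).
#' @export
artifact_params <- function(eeg_limit_mV = 0.2, emg_limit_mV = 1) {
  stopifnot(eeg_limit_mV > 0, emg_limit_mV > 0)
  structure(list(eeg_limit_uV = eeg_limit_mV * 1000,
                 emg_limit_uV = emg_limit_mV * 1000),
            class = "artifact_params")
}

#' Flag artifact epochs by amplitude limits
#'
#' An epoch is flagged when the absolute mean-removed EEG reaches the EEG
#' limit, or (when an EMG channel is present) the absolute mean-removed EMG
#' reaches the EMG limit. The channel mean is taken over the whole
#' recording, so a DC offset does not trip the limit. Comparison is
#' inclusive (`>=`) at the limit.
#'
#' @param recording a [telemetry_recording()] with at least an EEG channel.
#' @param grid an [segment_epochs()] grid.
#' @param params an [artifact_params()].
#' @return the grid with its `artifact` mask updated (OR-ed with any
#'   existing flags).
#' @export
flag_artifacts <- function(recording, grid, params = artifact_params()) {
  stopifnot(inherits(grid, "epoch_grid"), inherits(params, "artifact_params"))
  eeg <- channel_or_stop(recording, "EEG")
  emg <- recording$channels$EMG
  eeg0 <- abs(eeg$samples - mean(eeg$samples))
  emg0 <- if (!is.null(emg)) abs(emg$samples - mean(emg$samples))
  flagged <- vapply(grid$epoch_starts, function(s) {
    r <- epoch_sample_range(s, grid$epoch_length, eeg$sampling_rate, length(eeg0))
    hit <- max(eeg0[r[1]:r[2]]) >= params$eeg_limit_uV
    if (!hit && !is.null(emg0)) {
      re <- epoch_sample_range(s, grid$epoch_length, emg$sampling_rate, length(emg0))
      hit <- max(emg0[re[1]:re[2]]) >= params$emg_limit_uV
    }
    hit
  }, logical(1))
  grid$artifact <- grid$artifact | flagged
  grid
}
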