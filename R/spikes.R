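#' Epileptiform spike and spike-train detection parameters
#'
#' Defaults follow the standard rodent telemetry scoring rules: an absolute
#' amplitude threshold of 200 uV, spike duration between 1 and 200 ms,
#' inter-spike intervals between 0.05 and 0.5 s for chaining, and a train
#' defined by at least 3 spikes spanning at least 1 s.
#'
#' @param threshold_uV absolute amplitude threshold in microvolts.
#' @param min_spike_dur_ms,max_spike_dur_ms spike duration limits (ms).
#' @param isi_min_s,isi_max_s inter-spike (peak-to-peak) interval limits for
#'   train membership, inclusive at both ends (seconds).
#' @param min_spikes_per_train minimum spike count of a train.
#' @param min_train_time_s minimum train span, first to last peak (seconds).
#' @return a list of class `spike_params`.
#' @export
spike_params <- function(threshold_uV = 200,
                         min_spike_dur_ms = 1, max_spike_dur_ms = 200,
                         isi_min_s = 0.05, isi_max_s = 0.5,
                         min_spikes_per_train = 3, min_train_time_s = 1) {
  stopifnot(threshold_uV > 0,
            min_spike_dur_ms < max_spike_dur_ms,
            isi_min_s < isi_max_s,
            min_spikes_per_train >= 2)
  structure(list(threshold_uV = threshold_uV,
                 min_spike_dur_ms = min_spike_dur_ms,
                 max_spike_dur_ms = max_spike_dur_ms,
                 isi_min_s = isi_min_s, isi_max_s = isi_max_s,
                 min_spikes_per_train = min_spikes_per_train,
                 min_train_time_s = min_train_time_s),
            class = "spike_params")
}

#' Detect high-amplitude spikes in an EEG trace
#'
#' A spike event is a maximal contiguous run of samples whose mean-removed
#' absolute amplitude reaches the threshold (both polarities; the trace's
#' DC offset is removed first, so detection is offset-invariant). Runs
#' shorter than the minimum or longer than the maximum spike duration are
#' discarded. Events clipped by the recording edge are kept if the observed
#' run already satisfies the minimum duration.
#'
#' @param eeg numeric EEG vector in microvolts.
#' @param sampling_rate sampling rate in Hz (a warning is issued below
#'   500 Hz, where 1-ms events cannot be resolved well).
#' @param params a [spike_params()].
#' @return data frame of events, one row per spike: `onset_s`,
#'   `duration_ms`, `peak_uV` (signed, extremum of the run), `peak_time_s`.
#' @export
detect_spikes <- function(eeg, sampling_rate, params = spike_params()) {
  stopifnot(inherits(params, "spike_params"), sampling_rate > 0)
  bad <- which(!is.finite(eeg))
  if (length(bad)) stop("non-finite sample at index ", bad[1])
  if (sampling_rate < 500) {
    warning("sampling rate below 500 Hz; millisecond spike durations are poorly resolved")
  }
  empty <- data.frame(onset_s = numeric(0), duration_ms = numeric(0),
                      peak_uV = numeric(0), peak_time_s = numeric(0))
  x <- eeg - mean(eeg)
  over <- abs(x) >= params$threshold_uV
  if (!any(over)) return(empty)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- lapply(runs, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    dur_ms <- (i1 - i0 + 1L) / sampling_rate * 1000
    if (dur_ms < params$min_spike_dur_ms || dur_ms > params$max_spike_dur_ms) {
      return(NULL)
    }
    seg <- x[i0:i1]
    pk <- which.max(abs(seg))
    data.frame(onset_s = (i0 - 1L) / sampling_rate,
               duration_ms = dur_ms,
               peak_uV = seg[pk],
               peak_time_s = (i0 - 1L + pk - 1L) / sampling_rate)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Chain spikes into spike trains
#'
#' Greedy left-to-right chaining over time-ordered spikes: a spike joins the
#' current chain iff its peak-to-peak interval from the previous spike lies
#' in `[isi_min, isi_max]` (inclusive at both ends); the first interval
#' outside that window closes the chain and starts a new one. A closed
#' chain is reported as a train iff it has at least `min_spikes_per_train`
#' spikes and its span (last peak minus first peak) is at least
#' `min_train_time_s`.
#'
#' @param spikes spike event data frame from [detect_spikes()].
#' @param params a [spike_params()].
#' @return data frame of trains: `start_s`, `end_s`, `duration_s`,
#'   `n_spikes`.
#' @export
group_spike_trains <- function(spikes, params = spike_params()) {
  stopifnot(inherits(params, "spike_params"))
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), n_spikes = integer(0))
  if (is.null(spikes) || nrow(spikes) == 0) return(empty)
  pk <- spikes$peak_time_s
  if (is.unsorted(pk)) stop("spikes must be time-ordered by peak_time_s")
  trains <- list()
  close_chain <- function(first, last, count) {
    span <- pk[last] - pk[first]
    if (count >= params$min_spikes_per_train &&
        span >= params$min_train_time_s - 1e-12) {
      data.frame(start_s = pk[first], end_s = pk[last],
                 duration_s = span, n_spikes = as.integer(count))
    }
  }
  first <- 1L
  for (i in seq_along(pk)[-1]) {
    gap <- pk[i] - pk[i - 1L]
    if (gap < params$isi_min_s - 1e-12 || gap > params$isi_max_s + 1e-12) {
      trains[[length(trains) + 1L]] <- close_chain(first, i - 1L, i - first)
      first <- i
    }
  }
  trains[[length(trains) + 1L]] <- close_chain(first, length(pk),
                                               length(pk) - first + 1L)
  out <- do.call(rbind, trains)
  if (is.null(out)) empty else out
}

#' Summarize spiking over a recording
#'
#' @param trains train data frame from [group_spike_trains()].
#' @param spikes spike data frame from [detect_spikes()].
#' @param recording_duration recording length in seconds.
#' @return a list of class `spike_summary`: `train_count`,
#'   `total_train_duration_s`, `spike_count`, `recording_duration_s`, and,
#'   when the recording spans at least 24 h, `trains_per_24h` and
#'   `train_duration_s_per_24h`.
#' @export
summarize_spiking <- function(trains, spikes, recording_duration) {
  stopifnot(recording_duration > 0)
  out <- list(train_count = nrow(trains),
              total_train_duration_s = sum(trains$duration_s),
              spike_count = nrow(spikes),
              recording_duration_s = recording_duration)
  if (recording_duration >= 24 * 3600) {
    days <- recording_duration / (24 * 3600)
    out$trains_per_24h <- out$train_count / days
    out$train_duration_s_per_24h <- out$total_train_duration_s / days
  }
  structure(out, class = "spike_summary")
}

#' @export
print.spike_summary <- function(x, ...) {
  cat(sprintf("<spike_summary> %d trains (%.2f s total) from %d spikes over %.0f s\n",
              x$train_count, x$total_train_duration_s, x$spike_count,
              x$recording_duration_s))
  invisible(x)
}
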