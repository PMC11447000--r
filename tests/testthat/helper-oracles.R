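# Independent oracles used across tests. These re-derive expectations by
# brute force and must stay independent of the implementation paths they
# check.

# validate every reported train against the raw spike list: count, span and
# all consecutive peak-to-peak intervals inside [isi_min, isi_max]
validate_trains <- function(trains, spikes, params) {
  if (nrow(trains) == 0) return(TRUE)
  pk <- spikes$peak_time_s
  all(vapply(seq_len(nrow(trains)), function(i) {
    members <- pk[pk >= trains$start_s[i] - 1e-9 & pk <= trains$end_s[i] + 1e-9]
    gaps <- diff(members)
    length(members) == trains$n_spikes[i] &&
      length(members) >= params$min_spikes_per_train &&
      (max(members) - min(members)) >= params$min_train_time_s - 1e-9 &&
      all(gaps >= params$isi_min_s - 1e-9 & gaps <= params$isi_max_s + 1e-9)
  }, logical(1)))
}

# brute-force count of raster events inside a window
count_events_in <- function(raster, t0, t1) {
  sum(raster$events$spike_time >= t0 & raster$events$spike_time <= t1)
}

# quiet recording: low-amplitude white-noise EEG only
quiet_recording <- function(duration_s, noise_sd = 20, fs = 500, seed = 1) {
  withr::with_seed(seed,
    telemetry_recording(rnorm(duration_s * fs, sd = noise_sd), fs_eeg = fs))
}

# a trace with an isolated symmetric +/-A rectangular excursion pair, so the
# trace mean is exactly zero and amplitude boundaries are exact
boundary_trace <- function(amp, n_samples_each = 2, n_total = 5000,
                           at = c(1000, 3000)) {
  x <- numeric(n_total)
  x[at[1] + seq_len(n_samples_each)] <- amp
  x[at[2] + seq_len(n_samples_each)] <- -amp
  x
}

# duration-only stub for epoch-count arithmetic on recordings too long to
# hold in memory
duration_stub <- function(duration_s) {
  structure(list(duration = duration_s), class = "telemetry_recording")
}
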