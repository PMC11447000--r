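#' Default per-stage signal signatures for the sleep generator
#'
#' Amplitudes (microvolts) of the delta (1.5 Hz) and theta (6.5 Hz)
#' oscillations, broadband EEG noise sd, EMG noise sd, and mean activity
#' level emitted per stage. The oscillation frequencies sit inside the
#' default delta and theta bands regardless of the configurable band edges.
#' Defaults separate the stages the way rodent telemetry does: slow-wave
#' sleep with dominant delta and muscular atonia; paradoxical sleep with
#' dominant theta, minimal EMG and no movement; wake with mixed EEG,
#' moderate EMG and negligible activity; active wake with high EMG and
#' clear accelerometer activity. Amplitudes stay below the 0.2 mV EEG
#' artifact limit so clean epochs are not discarded as artifact.
#'
#' @return data frame with columns `stage`, `delta_amp`, `theta_amp`,
#'   `broadband_amp`, `emg_amp`, `activity`.
#' @export
stage_signatures <- function() {
  data.frame(
    stage = c("ACTIVE_WAKE", "WAKE", "SWS", "PARADOXICAL"),
    delta_amp = c(30, 25, 100, 15),
    theta_amp = c(50, 25, 20, 100),
    broadband_amp = c(25, 25, 15, 15),
    emg_amp = c(72, 60, 8, 4),
    activity = c(0.5, 0.02, 0, 0)
  )
}

#' Generate a first-order Markov stage sequence
#'
#' By default each stage persists with probability `stay` and otherwise
#' jumps uniformly to one of the other three, giving a uniform stationary
#' distribution with realistic bout structure.
#'
#' @param n_epochs number of epochs.
#' @param transition optional 4x4 row-stochastic matrix with rows/columns
#'   ordered active wake, wake, SWS, paradoxical.
#' @param stay persistence probability used when `transition` is NULL.
#' @param init initial stage label.
#' @param seed optional integer seed.
#' @return character vector of stage labels.
#' @export
generate_stage_sequence <- function(n_epochs, transition = NULL, stay = 0.75,
                                    init = "WAKE", seed = NULL) {
  stages <- sleep_stage_levels
  if (is.null(transition)) {
    transition <- matrix((1 - stay) / 3, 4, 4)
    diag(transition) <- stay
  }
  stopifnot(all(abs(rowSums(transition) - 1) < 1e-9), init %in% stages)
  gen <- function() {
    out <- character(n_epochs)
    cur <- match(init, stages)
    for (i in seq_len(n_epochs)) {
      out[i] <- stages[cur]
      cur <- sample.int(4, 1, prob = transition[cur, ])
    }
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a synthetic telemetry recording with known sleep architecture
#'
#' Per epoch, the EEG is the sum of a delta-band sinusoid (1.5 Hz), a
#' theta-band sinusoid (6.5 Hz) and white broadband noise, with amplitudes
#' set by the epoch's stage signature and phases randomized per epoch; the
#' EMG is white noise scaled by the stage's EMG amplitude; the activity
#' channel is the stage's level plus small truncated-at-zero jitter. The
#' same seed reproduces the recording bit for bit.
#'
#' @param stage_sequence character vector of per-epoch stage labels (see
#'   [generate_stage_sequence()]).
#' @param epoch_length epoch length in seconds (default 10).
#' @param signatures signature table from [stage_signatures()].
#' @param noise_sd additional EEG white-noise sd in microvolts applied in
#'   every stage (default 5).
#' @param fs_eeg,fs_activity sampling rates (EEG/EMG 500 Hz, activity
#'   200 Hz).
#' @param seed optional integer seed.
#' @return a list: `recording` (a [telemetry_recording()]) and `stages`
#'   (ground-truth data frame `epoch_start_s`, `stage`).
#' @export
generate_sleep_recording <- function(stage_sequence, epoch_length = 10,
                                     signatures = stage_signatures(),
                                     noise_sd = 5, fs_eeg = 500,
                                     fs_activity = 200, seed = NULL) {
  unknown <- setdiff(unique(stage_sequence), signatures$stage)
  if (length(unknown)) stop("unknown stage label: ", unknown[1])
  n_ep <- length(stage_sequence)
  if (n_ep < 1) stop("need at least one epoch")
  gen <- function() {
    ns <- round(epoch_length * fs_eeg)
    na <- round(epoch_length * fs_activity)
    t_eeg <- (seq_len(ns) - 1) / fs_eeg
    eeg <- numeric(n_ep * ns); emg <- numeric(n_ep * ns)
    act <- numeric(n_ep * na)
    for (i in seq_len(n_ep)) {
      sg <- signatures[signatures$stage == stage_sequence[i], ]
      ph <- stats::runif(2, 0, 2 * pi)
      e <- sg$delta_amp * sin(2 * pi * 1.5 * t_eeg + ph[1]) +
        sg$theta_amp * sin(2 * pi * 6.5 * t_eeg + ph[2]) +
        stats::rnorm(ns, sd = sg$broadband_amp)
      if (noise_sd > 0) e <- e + stats::rnorm(ns, sd = noise_sd)
      eeg[(i - 1) * ns + seq_len(ns)] <- e
      emg[(i - 1) * ns + seq_len(ns)] <- stats::rnorm(ns, sd = sg$emg_amp)
      act[(i - 1) * na + seq_len(na)] <-
        pmax(0, sg$activity + stats::rnorm(na, sd = 0.01))
    }
    list(recording = telemetry_recording(eeg, emg, act, fs_eeg = fs_eeg,
                                         fs_emg = fs_eeg,
                                         fs_activity = fs_activity),
         stages = data.frame(epoch_start_s = (seq_len(n_ep) - 1) * epoch_length,
                             stage = stage_sequence))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# biphasic spike template: half-sine main lobe (60% of the width) at full
# amplitude followed by a 20%-amplitude undershoot, so only the main lobe
# crosses the 200 uV detection threshold
spike_waveform <- function(amp, dur_ms, fs) {
  n <- max(3L, round(dur_ms / 1000 * fs))
  n1 <- max(2L, round(0.6 * n))
  n2 <- n - n1
  main <- amp * sin(pi * (seq_len(n1) - 0.5) / n1)
  under <- if (n2 > 0) -0.2 * amp * sin(pi * (seq_len(n2) - 0.5) / n2) else numeric(0)
  structure(c(main, under), peak_offset = which.max(abs(main)) - 1L)
}

#' Plant epileptiform spike trains into a recording
#'
#' Adds biphasic spike waveforms to the EEG channel at fixed intra-train
#' inter-spike intervals, returning the exact planted train intervals as
#' ground truth. When no insertion times are given, trains are placed one
#' per equal slot of the recording with a random in-slot offset, keeping at
#' least `2 * 0.5 s` of silence between trains so plants never chain
#' together.
#'
#' @param recording a [telemetry_recording()].
#' @param n_trains number of trains to plant.
#' @param spikes_per_train spikes per train (default 5).
#' @param isi_s intra-train peak-to-peak interval in seconds (default 0.3;
#'   keep within `[0.05, 0.5]` so plants are chainable by design).
#' @param spike_amp_uV main-lobe amplitude in microvolts (default 400;
#'   below 200 the plants are sub-threshold by construction).
#' @param spike_dur_ms spike width in ms (default 10).
#' @param insertion_times optional vector of train start times in seconds.
#' @param seed optional integer seed (used for random placement).
#' @return a list: `recording` (EEG modified) and `trains` (ground truth:
#'   `start_s`, `end_s`, `n_spikes`).
#' @export
inject_spike_trains <- function(recording, n_trains, spikes_per_train = 5,
                                isi_s = 0.3, spike_amp_uV = 400,
                                spike_dur_ms = 10, insertion_times = NULL,
                                seed = NULL) {
  stopifnot(inherits(recording, "telemetry_recording"),
            n_trains >= 0, spikes_per_train >= 1, isi_s > 0)
  truth <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0))
  if (n_trains == 0) return(list(recording = recording, trains = truth))
  span <- (spikes_per_train - 1) * isi_s
  guard <- 1  # 2 * max chaining interval of silence around each train
  if (is.null(insertion_times)) {
    slot <- recording$duration / n_trains
    if (slot < span + 2 * guard) {
      stop("recording too short to place ", n_trains, " non-chaining trains")
    }
    place <- function() (seq_len(n_trains) - 1) * slot + guard +
      stats::runif(n_trains, 0, slot - span - 2 * guard)
    insertion_times <- if (is.null(seed)) place() else withr::with_seed(seed, place())
  }
  if (length(insertion_times) != n_trains) {
    stop("insertion_times must have length n_trains")
  }
  if (any(insertion_times < 0) ||
      any(insertion_times + span + spike_dur_ms / 1000 > recording$duration)) {
    stop("insertion beyond recording end")
  }
  if (n_trains > 1 && min(diff(sort(insertion_times))) < span + 2 * 0.5) {
    stop("insertion windows overlap or chain together")
  }
  eeg <- recording$channels$EEG
  fs <- eeg$sampling_rate
  wf <- spike_waveform(spike_amp_uV, spike_dur_ms, fs)
  x <- eeg$samples
  first_peak <- last_peak <- numeric(n_trains)
  for (k in seq_len(n_trains)) {
    peaks <- numeric(spikes_per_train)
    for (j in seq_len(spikes_per_train)) {
      t0 <- insertion_times[k] + (j - 1) * isi_s
      i0 <- round(t0 * fs) + 1L
      idx <- i0:(i0 + length(wf) - 1L)
      x[idx] <- x[idx] + wf
      peaks[j] <- (i0 - 1L + attr(wf, "peak_offset")) / fs
    }
    first_peak[k] <- peaks[1]; last_peak[k] <- peaks[spikes_per_train]
  }
  recording$channels$EEG$samples <- x
  list(recording = recording,
       trains = data.frame(start_s = first_peak, end_s = last_peak,
                           n_spikes = as.integer(spikes_per_train)))
}

#' Generate a synthetic MEA spike raster with planted network bursts
#'
#' Per-electrode inhomogeneous Poisson process: `baseline_rate_hz` outside
#' burst windows and `baseline_rate_hz * burst_rate_multiplier` inside
#' them. Burst windows of length `burst_duration_s` are centred on
#' `burst_times`. Ground truth (window edges and centres) is returned
#' alongside.
#'
#' @param n_electrodes number of recorded electrodes.
#' @param baseline_rate_hz baseline per-electrode firing rate.
#' @param duration_s recording duration.
#' @param burst_times burst centre times in seconds (empty for homogeneous
#'   Poisson).
#' @param burst_duration_s burst window length (default 0.3).
#' @param burst_rate_multiplier rate multiplier inside bursts (1 means no
#'   bursts).
#' @param n_electrodes_total chip capacity (defaults to `n_electrodes`).
#' @param seed optional integer seed.
#' @return a list: `raster` (a [spike_raster()]) and `bursts` (ground
#'   truth: `center_s`, `start_s`, `end_s`).
#' @export
generate_raster <- function(n_electrodes, baseline_rate_hz, duration_s,
                            burst_times = numeric(0), burst_duration_s = 0.3,
                            burst_rate_multiplier = 1,
                            n_electrodes_total = n_electrodes, seed = NULL) {
  stopifnot(n_electrodes >= 1, baseline_rate_hz >= 0, duration_s >= 0)
  w <- burst_duration_s
  if (length(burst_times) &&
      (min(burst_times) - w / 2 < 0 || max(burst_times) + w / 2 > duration_s)) {
    stop("burst windows must lie within the recording")
  }
  gen <- function() {
    n_base <- stats::rpois(1, n_electrodes * baseline_rate_hz * duration_s)
    times <- stats::runif(n_base, 0, duration_s)
    ids <- sample.int(n_electrodes, n_base, replace = TRUE) - 1L
    extra_rate <- n_electrodes * baseline_rate_hz * (burst_rate_multiplier - 1) * w
    for (ct in burst_times) {
      n_extra <- stats::rpois(1, extra_rate)
      times <- c(times, stats::runif(n_extra, ct - w / 2, ct + w / 2))
      ids <- c(ids, sample.int(n_electrodes, n_extra, replace = TRUE) - 1L)
    }
    spike_raster(ids, times, duration_s, n_electrodes_total = n_electrodes_total)
  }
  raster <- if (duration_s == 0 || n_electrodes * baseline_rate_hz == 0) {
    spike_raster(integer(0), numeric(0), duration_s,
                 n_electrodes_total = n_electrodes_total)
  } else if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  truth <- data.frame(center_s = burst_times,
                      start_s = burst_times - w / 2,
                      end_s = burst_times + w / 2)
  list(raster = raster, bursts = truth)
}
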