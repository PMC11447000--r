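#' Sleep-stage membership anchors
#'
#' The scorer uses piecewise-linear membership functions that saturate at
#' fixed anchor values of three dimensionless ratio features, plus an
#' accelerometer rule:
#' * delta ratio (epoch delta power over recording-mean delta power):
#'   slow-wave-sleep evidence is 0 at or below `delta_paradoxical_wake` and
#'   saturates at `delta_sws`;
#' * theta:delta ratio: paradoxical-sleep evidence is 0 at or below
#'   `theta_wake_sws` and saturates at `theta_paradoxical`;
#' * EMG ratio (epoch EMG power over recording-mean EMG power): wake
#'   evidence is 0 at or below `emg_paradoxical_sws` and saturates at
#'   `emg_wake`;
#' * any epoch whose mean activity exceeds `activity_active_wake`, or whose
#'   EMG ratio reaches `emg_active_wake_factor` times `emg_wake`, is scored
#'   active wake outright.
#'
#' @param delta_paradoxical_wake,delta_sws delta-ratio anchors (default
#'   0.5 and 1).
#' @param theta_wake_sws,theta_paradoxical theta:delta anchors (default 1.3
#'   and 3).
#' @param emg_paradoxical_sws,emg_wake EMG-ratio anchors (default 1 and
#'   2.4).
#' @param activity_active_wake activity level above which an epoch is
#'   active wake (default 0.1, strict `>`).
#' @param emg_active_wake_factor multiple of `emg_wake` at which EMG alone
#'   forces active wake (default 1.5, i.e. EMG ratio >= 3.6).
#' @return a list of class `stage_anchors`.
#' @export
stage_anchors <- function(delta_paradoxical_wake = 0.5, delta_sws = 1,
                          theta_wake_sws = 1.3, theta_paradoxical = 3,
                          emg_paradoxical_sws = 1, emg_wake = 2.4,
                          activity_active_wake = 0.1,
                          emg_active_wake_factor = 1.5) {
  stopifnot(delta_paradoxical_wake < delta_sws,
            theta_wake_sws < theta_paradoxical,
            emg_paradoxical_sws < emg_wake,
            activity_active_wake > 0, emg_active_wake_factor > 0)
  structure(as.list(environment()), class = "stage_anchors")
}

sleep_stage_levels <- c("ACTIVE_WAKE", "WAKE", "SWS", "PARADOXICAL")

#' Per-epoch sleep-staging features
#'
#' For each 10-s epoch: delta power and theta power from the epoch's own
#' Hamming periodogram, EMG power as the epoch variance of the mean-removed
#' EMG, and the mean activity level. Delta and EMG powers are normalized by
#' their recording-wide means over non-artifact epochs, making the anchor
#' thresholds scale-free. Artifact epochs carry NA features.
#'
#' @param recording a [telemetry_recording()] with EEG, EMG and ACTIVITY
#'   channels.
#' @param grid a 10-s [segment_epochs()] grid (built and artifact-flagged
#'   if omitted).
#' @param bands band table from [eeg_bands()] (delta and theta rows used).
#' @param artifact [artifact_params()] used when `grid` is NULL.
#' @return data frame per epoch: `epoch_start_s`, `delta_ratio`,
#'   `theta_delta_ratio` (NA when the epoch delta power is 0),
#'   `emg_ratio`, `activity`, `artifact`.
#' @export
compute_stage_features <- function(recording, grid = NULL,
                                   bands = eeg_bands(),
                                   artifact = artifact_params()) {
  eeg <- channel_or_stop(recording, "EEG")
  emg <- channel_or_stop(recording, "EMG")
  act <- channel_or_stop(recording, "ACTIVITY")
  if (is.null(grid)) {
    grid <- flag_artifacts(recording, segment_epochs(recording, 10), artifact)
  }
  n <- length(grid$epoch_starts)
  if (n < 6) stop("need at least 6 epochs for stable self-normalization")
  db <- bands[bands$band == "delta", ]
  tb <- bands[bands$band == "theta", ]
  delta <- theta <- emg_p <- act_m <- rep(NA_real_, n)
  for (i in which(!grid$artifact)) {
    s <- grid$epoch_starts[i]
    sp <- compute_psd(epoch_samples(eeg, s, grid$epoch_length),
                      eeg$sampling_rate)
    delta[i] <- band_power(sp, db$low, db$high)
    theta[i] <- band_power(sp, tb$low, tb$high)
    e <- epoch_samples(emg, s, grid$epoch_length)
    emg_p[i] <- mean((e - mean(e))^2)
    a <- epoch_samples(act, s, grid$epoch_length)
    act_m[i] <- mean(a)
  }
  delta_mean <- mean(delta, na.rm = TRUE)
  emg_mean <- mean(emg_p, na.rm = TRUE)
  data.frame(
    epoch_start_s = grid$epoch_starts,
    delta_ratio = if (delta_mean > 0) delta / delta_mean else NA_real_,
    theta_delta_ratio = ifelse(delta > 0, theta / delta, NA_real_),
    emg_ratio = if (emg_mean > 0) emg_p / emg_mean else NA_real_,
    activity = act_m,
    artifact = grid$artifact
  )
}

# membership ramp rising 0 -> 1 between lo and hi
ramp <- function(x, lo, hi) clamp01((x - lo) / (hi - lo))

#' Stage probabilities from features
#'
#' Each feature contributes one evidence vector over the four stages
#' (active wake, wake, SWS, paradoxical):
#' * delta: SWS weight ramps from 0 at the paradoxical/wake anchor to 1 at
#'   the SWS anchor; the complement is split equally between wake and
#'   paradoxical;
#' * theta:delta: paradoxical weight ramps between its anchors; complement
#'   split equally between wake and SWS;
#' * EMG: wake weight ramps between its anchors; complement split equally
#'   between SWS and paradoxical;
#' * activity: active-wake weight 1 if activity exceeds the active-wake
#'   level, else 0; complement split equally over the other three stages.
#'
#' The four evidence vectors are averaged with equal weights (each already
#' sums to 1). An undefined theta:delta ratio contributes a uniform vector.
#'
#' @param features data frame from [compute_stage_features()] (or any data
#'   frame with `delta_ratio`, `theta_delta_ratio`, `emg_ratio`,
#'   `activity`).
#' @param anchors a [stage_anchors()].
#' @return numeric matrix, one row per epoch, columns
#'   `ACTIVE_WAKE`, `WAKE`, `SWS`, `PARADOXICAL`; rows sum to 1
#'   (NA for artifact/undefined epochs).
#' @export
stage_probabilities <- function(features, anchors = stage_anchors()) {
  stopifnot(inherits(anchors, "stage_anchors"))
  n <- nrow(features)
  probs <- matrix(NA_real_, n, 4, dimnames = list(NULL, sleep_stage_levels))
  for (i in seq_len(n)) {
    f <- features[i, ]
    if (any(is.na(c(f$delta_ratio, f$emg_ratio, f$activity)))) next
    s <- ramp(f$delta_ratio, anchors$delta_paradoxical_wake, anchors$delta_sws)
    ev_delta <- c(0, (1 - s) / 2, s, (1 - s) / 2)
    if (is.na(f$theta_delta_ratio)) {
      ev_theta <- rep(0.25, 4)
    } else {
      t_ <- ramp(f$theta_delta_ratio, anchors$theta_wake_sws,
                 anchors$theta_paradoxical)
      ev_theta <- c(0, (1 - t_) / 2, (1 - t_) / 2, t_)
    }
    e <- ramp(f$emg_ratio, anchors$emg_paradoxical_sws, anchors$emg_wake)
    ev_emg <- c(0, e, (1 - e) / 2, (1 - e) / 2)
    ev_act <- if (f$activity > anchors$activity_active_wake) {
      c(1, 0, 0, 0)
    } else {
      c(0, 1, 1, 1) / 3
    }
    p <- (ev_delta + ev_theta + ev_emg + ev_act) / 4
    probs[i, ] <- p / sum(p)
  }
  probs
}

#' Classify epochs into sleep stages
#'
#' Override first: an epoch is active wake when its activity exceeds the
#' active-wake level (strict `>`) or its EMG ratio reaches
#' `emg_active_wake_factor * emg_wake` (inclusive `>=`). Otherwise the
#' stage is the argmax of the probability vector, with exact ties broken in
#' the fixed order wake > SWS > paradoxical > active wake.
#'
#' @param probs probability matrix from [stage_probabilities()].
#' @param features matching feature data frame.
#' @param anchors a [stage_anchors()].
#' @return data frame `stage` (factor over the four stages plus ARTIFACT)
#'   and `override` (logical, TRUE where the active-wake override fired).
#' @export
classify_epochs <- function(probs, features, anchors = stage_anchors()) {
  stopifnot(nrow(probs) == nrow(features))
  tie_order <- c("WAKE", "SWS", "PARADOXICAL", "ACTIVE_WAKE")
  n <- nrow(probs)
  stage <- character(n)
  override <- logical(n)
  emg_aw <- anchors$emg_active_wake_factor * anchors$emg_wake
  for (i in seq_len(n)) {
    if (any(is.na(probs[i, ]))) {
      stage[i] <- "ARTIFACT"
      next
    }
    f <- features[i, ]
    if (f$activity > anchors$activity_active_wake ||
        (!is.na(f$emg_ratio) && f$emg_ratio >= emg_aw)) {
      stage[i] <- "ACTIVE_WAKE"
      override[i] <- TRUE
    } else {
      p <- probs[i, tie_order]
      stage[i] <- tie_order[which.max(p)]  # which.max: first max in tie order
    }
  }
  data.frame(stage = factor(stage, levels = c(sleep_stage_levels, "ARTIFACT")),
             override = override)
}

#' Score a recording into a hypnogram
#'
#' Full staging chain: 10-s epoching, artifact flagging, feature
#' extraction, membership probabilities, override and argmax
#' classification.
#'
#' @param recording a [telemetry_recording()] with EEG, EMG and ACTIVITY
#'   channels.
#' @param anchors a [stage_anchors()].
#' @param bands band table from [eeg_bands()].
#' @param artifact [artifact_params()].
#' @return an object of class `hypnogram`: data frame `epoch_start_s`,
#'   `stage`, `p_active_wake`, `p_wake`, `p_sws`, `p_paradoxical`,
#'   `override`; attribute `epoch_length` (10 s).
#' @export
stage_recording <- function(recording, anchors = stage_anchors(),
                            bands = eeg_bands(), artifact = artifact_params()) {
  grid <- flag_artifacts(recording, segment_epochs(recording, 10), artifact)
  feats <- compute_stage_features(recording, grid, bands)
  probs <- stage_probabilities(feats, anchors)
  cls <- classify_epochs(probs, feats, anchors)
  hyp <- data.frame(epoch_start_s = feats$epoch_start_s,
                    stage = cls$stage,
                    p_active_wake = probs[, "ACTIVE_WAKE"],
                    p_wake = probs[, "WAKE"],
                    p_sws = probs[, "SWS"],
                    p_paradoxical = probs[, "PARADOXICAL"],
                    override = cls$override)
  structure(hyp, epoch_length = 10, class = c("hypnogram", "data.frame"))
}

#' Summarize a hypnogram into stage percentages
#'
#' @param hypnogram a `hypnogram` (or any data frame with a `stage` column
#'   and an `epoch_length` attribute).
#' @return a list of class `sleep_summary`: `percent` (named vector over
#'   the four stages, summing to 100 over scored epochs), `scored_hours`,
#'   `artifact_fraction`, `n_epochs`.
#' @export
summarize_hypnogram <- function(hypnogram) {
  st <- as.character(hypnogram$stage)
  scored <- st[st != "ARTIFACT"]
  if (!length(scored)) stop("no scored (non-artifact) epochs")
  pct <- vapply(sleep_stage_levels,
                function(s) 100 * mean(scored == s), numeric(1))
  len <- attr(hypnogram, "epoch_length")
  if (is.null(len)) len <- 10
  structure(list(percent = pct,
                 scored_hours = length(scored) * len / 3600,
                 artifact_fraction = mean(st == "ARTIFACT"),
                 n_epochs = length(st)),
            class = "sleep_summary")
}

#' @export
print.sleep_summary <- function(x, ...) {
  cat(sprintf("<sleep_summary> %.2f h scored (%.1f%% artifact)\n",
              x$scored_hours, 100 * x$artifact_fraction))
  print(round(x$percent, 2))
  invisible(x)
}
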