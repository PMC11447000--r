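#' Construct a spike raster
#'
#' Event-list representation of extracellular spikes on a high-density
#' microelectrode array: one row per detected spike, identified by
#' electrode and time. The full chip carries 26,400 electrodes; network
#' assays record a 1024-electrode subset for 300 s.
#'
#' @param electrode_id integer electrode ids (0-based, `< n_electrodes_total`).
#' @param spike_time spike times in seconds, within `[0, duration]`.
#' @param duration recording duration in seconds.
#' @param n_electrodes_total chip capacity (default 26400).
#' @param selected_electrodes optional electrode subset the assay recorded.
#' @return an object of class `spike_raster` with a data frame `events`
#'   (sorted by time), `duration`, `n_electrodes_total`,
#'   `selected_electrodes`.
#' @export
spike_raster <- function(electrode_id, spike_time, duration,
                         n_electrodes_total = 26400,
                         selected_electrodes = NULL) {
  stopifnot(length(electrode_id) == length(spike_time), duration >= 0)
  if (length(spike_time) &&
      (min(spike_time) < 0 || max(spike_time) > duration + 1e-9)) {
    stop("spike times must lie within [0, duration]")
  }
  if (length(electrode_id) && max(electrode_id) >= n_electrodes_total) {
    stop("electrode_id must be < n_electrodes_total")
  }
  o <- order(spike_time)
  structure(list(events = data.frame(electrode_id = as.integer(electrode_id[o]),
                                     spike_time = spike_time[o]),
                 duration = duration,
                 n_electrodes_total = n_electrodes_total,
                 selected_electrodes = selected_electrodes),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d events on %d electrodes over %.0f s\n",
              nrow(x$events), length(unique(x$events$electrode_id)),
              x$duration))
  invisible(x)
}

#' Per-electrode firing rates from an activity scan
#'
#' The activity scan surveys each electrode for a fixed window (30 s on
#' MaxWell-style chips); the rate is simply spike count over scan duration.
#' Electrodes with no events appear with rate 0.
#'
#' @param raster a [spike_raster()].
#' @param scan_duration per-electrode scan window in seconds (default 30).
#' @return data frame `electrode_id`, `rate_hz`, one row per electrode of
#'   the chip, ordered by electrode id.
#' @export
summarize_activity_scan <- function(raster, scan_duration = 30) {
  stopifnot(inherits(raster, "spike_raster"), scan_duration > 0)
  ids <- 0:(raster$n_electrodes_total - 1L)
  counts <- tabulate(raster$events$electrode_id + 1L,
                     nbins = raster$n_electrodes_total)
  data.frame(electrode_id = ids, rate_hz = counts / scan_duration)
}

#' Select the highest-firing electrodes
#'
#' Picks the `n` electrodes with the highest activity-scan firing rate for
#' the network assay; ties at the cutoff are broken by ascending electrode
#' id, so the selection is deterministic.
#'
#' @param scan activity-scan data frame from [summarize_activity_scan()].
#' @param n number of electrodes to select (default 1024).
#' @return integer vector of `n` electrode ids.
#' @export
select_top_electrodes <- function(scan, n = 1024) {
  stopifnot(is.data.frame(scan), all(c("electrode_id", "rate_hz") %in% names(scan)))
  if (nrow(scan) < n) {
    stop("only ", nrow(scan), " electrodes scanned; cannot select ", n)
  }
  o <- order(-scan$rate_hz, scan$electrode_id)
  scan$electrode_id[o[seq_len(n)]]
}

#' Network-burst detection parameters
#'
#' The population firing rate is a Gaussian-smoothed histogram of pooled
#' spike times. Bursts are peaks of that rate above `mean + k sd`,
#' separated by at least `min_peak_separation`, with edges where the rate
#' falls below `boundary_fraction` of the peak height (or below the
#' threshold, whichever crossing is nearer the peak). Candidate bursts with
#' fewer than `min_spikes` participating spikes are discarded.
#'
#' @param bin_width histogram bin width in seconds (default 0.01).
#' @param gaussian_sigma smoothing kernel sd in seconds (default 0.1);
#'   kernel truncated at four sigma.
#' @param threshold_k multiplier `k` in the `mean + k sd` threshold
#'   (default 3).
#' @param min_spikes minimum pooled spikes per burst (default 50).
#' @param min_peak_separation minimum peak-to-peak separation in seconds
#'   (default 0.2).
#' @param boundary_fraction fraction of peak height defining burst edges
#'   (default 0.1).
#' @return a list of class `burst_params`.
#' @export
burst_params <- function(bin_width = 0.01, gaussian_sigma = 0.1,
                         threshold_k = 3, min_spikes = 50,
                         min_peak_separation = 0.2, boundary_fraction = 0.1) {
  stopifnot(bin_width > 0, gaussian_sigma >= bin_width,
            boundary_fraction > 0, boundary_fraction < 1,
            min_peak_separation >= 0, min_spikes >= 1)
  structure(as.list(environment()), class = "burst_params")
}

#' Gaussian-smoothed population firing rate
#'
#' Pools all spike times, bins them at `bin_width`, and convolves with a
#' unit-area Gaussian kernel of sd `gaussian_sigma` (truncated at four
#' sigma, renormalized). The time grid is padded by four sigma on both
#' sides so the rate integral conserves the pooled spike count.
#'
#' @param raster a [spike_raster()] with `duration >= 10 * gaussian_sigma`.
#' @param params a [burst_params()].
#' @return an object of class `population_rate`: `time` (bin centres,
#'   seconds; extends slightly beyond the recording because of padding),
#'   `rate` (pooled spikes/s), `bin_width`, `params`.
#' @export
population_rate <- function(raster, params = burst_params()) {
  stopifnot(inherits(raster, "spike_raster"), inherits(params, "burst_params"))
  if (raster$duration < 10 * params$gaussian_sigma) {
    stop("recording shorter than 10 smoothing sigmas")
  }
  bw <- params$bin_width
  pad <- 4 * params$gaussian_sigma
  edges <- seq(-pad, raster$duration + pad + bw, by = bw)
  counts <- if (nrow(raster$events)) {
    tabulate(findInterval(raster$events$spike_time, edges),
             nbins = length(edges) - 1L)
  } else {
    integer(length(edges) - 1L)
  }
  kt <- seq(-pad, pad, by = bw)
  kern <- stats::dnorm(kt, sd = params$gaussian_sigma)
  kern <- kern / sum(kern)
  # direct convolution on a zero-extended vector: exact (no FFT round-off)
  # and fast for the short truncated kernel
  hw <- (length(kern) - 1L) / 2L
  padded <- c(numeric(hw), counts, numeric(hw))
  sm <- stats::filter(padded, kern, sides = 2)
  sm <- as.numeric(sm[(hw + 1L):(hw + length(counts))])
  structure(list(time = edges[-length(edges)] + bw / 2,
                 rate = sm / bw, bin_width = bw, params = params),
            class = "population_rate")
}

#' Detect network bursts from the population rate
#'
#' Local maxima of the smoothed rate above the `mean + k sd` threshold
#' become candidate peaks; peaks closer than `min_peak_separation` to a
#' higher accepted peak are suppressed. Edges extend outward from each peak
#' to the first bin where the rate falls below the inner of the two stop
#' levels (`boundary_fraction * peak` or the threshold). Overlapping bursts
#' are merged keeping the higher peak, and bursts with fewer than
#' `min_spikes` raw events are dropped. Spike and electrode counts are
#' tallied from the raw event list within `[start, end]`.
#'
#' @param rate a [population_rate()] computed from `raster` with the same
#'   `params`.
#' @param raster the matching [spike_raster()].
#' @param params a [burst_params()].
#' @return data frame, one row per burst, sorted by peak time:
#'   `peak_time_s`, `start_s`, `end_s`, `duration_s`, `peak_rate_hz`,
#'   `n_spikes`, `n_electrodes`.
#' @export
detect_network_bursts <- function(rate, raster, params = burst_params()) {
  stopifnot(inherits(rate, "population_rate"), inherits(raster, "spike_raster"))
  empty <- data.frame(peak_time_s = numeric(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      peak_rate_hz = numeric(0), n_spikes = integer(0),
                      n_electrodes = integer(0))
  r <- rate$rate
  n <- length(r)
  if (n < 3) return(empty)
  thr <- mean(r) + params$threshold_k * stats::sd(r)
  cand <- which(r[-c(1, n)] > r[-c(n - 1, n)] & r[-c(1, n)] >= r[-c(1, 2)] &
                  r[-c(1, n)] > thr) + 1L
  if (!length(cand)) return(empty)
  # enforce minimum peak separation, highest peaks first
  cand <- cand[order(-r[cand])]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) ||
        all(abs(rate$time[i] - rate$time[kept]) >= params$min_peak_separation)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  # walk edges out to the inner stop level
  bursts <- lapply(kept, function(i) {
    stop_level <- max(params$boundary_fraction * r[i], thr)
    i0 <- i
    while (i0 > 1L && r[i0 - 1L] >= stop_level) i0 <- i0 - 1L
    i1 <- i
    while (i1 < n && r[i1 + 1L] >= stop_level) i1 <- i1 + 1L
    c(peak = i, start = i0, end = i1)
  })
  b <- do.call(rbind, bursts)
  # merge overlapping bursts, keeping the higher peak
  o <- order(-r[b[, "peak"]])
  keep <- rep(TRUE, nrow(b))
  for (j in seq_along(o)) {
    if (!keep[o[j]]) next
    for (k in o[-seq_len(j)]) {
      if (keep[k] &&
          b[k, "start"] <= b[o[j], "end"] && b[k, "end"] >= b[o[j], "start"]) {
        keep[k] <- FALSE
      }
    }
  }
  b <- b[keep, , drop = FALSE]
  b <- b[order(b[, "peak"]), , drop = FALSE]
  st <- raster$events$spike_time
  out <- lapply(seq_len(nrow(b)), function(j) {
    t0 <- rate$time[b[j, "start"]] - rate$bin_width / 2
    t1 <- rate$time[b[j, "end"]] + rate$bin_width / 2
    sel <- st >= t0 & st <= t1
    data.frame(peak_time_s = rate$time[b[j, "peak"]],
               start_s = t0, end_s = t1, duration_s = t1 - t0,
               peak_rate_hz = r[b[j, "peak"]],
               n_spikes = sum(sel),
               n_electrodes = length(unique(raster$events$electrode_id[sel])))
  })
  out <- do.call(rbind, out)
  out <- out[out$n_spikes >= params$min_spikes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Burst metrics over a network assay
#'
#' The inter-burst interval (IBI) is the time between consecutive burst
#' peaks; it is undefined (NA) with fewer than two bursts.
#'
#' @param bursts burst data frame from [detect_network_bursts()],
#'   time-ordered.
#' @param duration assay duration in seconds (default 300).
#' @return a list of class `burst_metrics`: `n_bursts`, `mean_ibi_s`,
#'   `mean_burst_duration_s`, `mean_spikes_per_burst`, `burst_rate_per_min`.
#' @export
burst_metrics <- function(bursts, duration = 300) {
  nb <- nrow(bursts)
  structure(list(
    n_bursts = nb,
    mean_ibi_s = if (nb >= 2) mean(diff(bursts$peak_time_s)) else NA_real_,
    mean_burst_duration_s = if (nb >= 1) mean(bursts$duration_s) else NA_real_,
    mean_spikes_per_burst = if (nb >= 1) mean(bursts$n_spikes) else NA_real_,
    burst_rate_per_min = nb / duration * 60
  ), class = "burst_metrics")
}

#' @export
print.burst_metrics <- function(x, ...) {
  cat(sprintf("<burst_metrics> %d bursts; IBI %.3f s; duration %.3f s; %.1f spikes/burst\n",
              x$n_bursts, x$mean_ibi_s, x$mean_burst_duration_s,
              x$mean_spikes_per_burst))
  invisible(x)
}
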