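#' Power spectral density of one epoch
#'
#' Single Hamming-windowed periodogram of the mean-removed epoch, scaled so
#' that integrating the density over frequency recovers the sample variance
#' (the window power correction `sum(w^2)` is applied). One-sided: interior
#' frequencies carry doubled density. Native resolution is
#' `1 / epoch_length` Hz.
#'
#' @param epoch_samples numeric vector, one epoch of signal (microvolts).
#' @param sampling_rate sampling rate in Hz.
#' @param fmax upper frequency cutoff in Hz; frequencies above it are
#'   dropped (default 50, the analysis band). Use `Inf` for the full
#'   one-sided spectrum up to Nyquist.
#' @return an object of class `power_spectrum`: `frequency` (Hz), `power`
#'   (uV^2/Hz), `resolution` (Hz).
#' @examples
#' fs <- 500
#' x <- 50 * sin(2 * pi * 2 * seq(0, 30 - 1/fs, by = 1/fs))
#' sp <- compute_psd(x, fs)
#' # total power approximately a^2 / 2 = 1250 uV^2
#' psd_integral(sp)
#' @export
compute_psd <- function(epoch_samples, sampling_rate, fmax = 50) {
  stopifnot(length(epoch_samples) >= 2, sampling_rate > 0)
  bad <- which(!is.finite(epoch_samples))
  if (length(bad)) stop("non-finite sample at index ", bad[1])
  n <- length(epoch_samples)
  w <- signal::hamming(n)
  xw <- (epoch_samples - mean(epoch_samples)) * w
  X <- stats::fft(xw)
  nf <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(nf)])^2 / (sampling_rate * sum(w^2))
  # one-sided doubling (DC and, for even n, Nyquist are not doubled)
  if (nf > 2L) {
    last_double <- if (n %% 2L == 0L) nf - 1L else nf
    p[2:last_double] <- 2 * p[2:last_double]
  }
  f <- (seq_len(nf) - 1) * sampling_rate / n
  keep <- f <= fmax + 1e-12
  structure(list(frequency = f[keep], power = p[keep],
                 resolution = sampling_rate / n),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d frequencies, %g-%g Hz, resolution %g Hz\n",
              length(x$frequency), min(x$frequency), max(x$frequency),
              x$resolution))
  invisible(x)
}

#' Integrate a power spectrum over a frequency interval
#'
#' Rectangle-rule integral of the density over the half-open interval
#' `[low, high)`: grid frequencies are assigned to the interval containing
#' them, so adjacent bands partition without double counting.
#'
#' @param spectrum a `power_spectrum`.
#' @param low,high interval edges in Hz.
#' @return integrated power (uV^2).
#' @export
psd_integral <- function(spectrum, low = 0, high = Inf) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  sel <- spectrum$frequency >= low - 1e-12 & spectrum$frequency < high - 1e-12
  sum(spectrum$power[sel]) * spectrum$resolution
}

#' Bin a power spectrum into fixed-width segments
#'
#' Density is averaged within each half-open bin `[k w, (k+1) w)` and
#' reported at the bin centre. Because the native grid is much finer than
#' the bin width, the binned integral conserves the native integral.
#'
#' @param spectrum a `power_spectrum`.
#' @param bin_width bin width in Hz (reporting convention: 2 Hz).
#' @return a `power_spectrum` at the binned resolution.
#' @export
bin_psd <- function(spectrum, bin_width = 2) {
  stopifnot(inherits(spectrum, "power_spectrum"), bin_width > 0)
  f <- spectrum$frequency
  idx <- floor(f / bin_width + 1e-9)
  # a frequency sitting exactly on the top edge would open a singleton bin;
  # half-open binning excludes it
  n_bins <- max(idx) + 1L
  top <- max(f)
  if (abs(top - bin_width * round(top / bin_width)) < 1e-9) {
    drop <- idx >= round(top / bin_width)
    idx <- idx[!drop]; fkeep <- f[!drop]; pkeep <- spectrum$power[!drop]
    n_bins <- round(top / bin_width)
  } else {
    fkeep <- f; pkeep <- spectrum$power
  }
  p <- vapply(seq_len(n_bins) - 1L, function(k) mean(pkeep[idx == k]), numeric(1))
  structure(list(frequency = (seq_len(n_bins) - 0.5) * bin_width,
                 power = p, resolution = bin_width),
            class = "power_spectrum")
}

#' Canonical EEG band definitions
#'
#' Default edges: delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30,
#' gamma 30-50 Hz. Bands are half-open `[low, high)`, so adjacent bands
#' tile 0.5-50 Hz with a shared edge owned by the upper band (4 Hz belongs
#' to theta).
#'
#' @param delta,theta,alpha,beta,gamma length-2 numeric `c(low, high)` edges
#'   in Hz.
#' @return a data frame with columns `band`, `low`, `high`.
#' @export
eeg_bands <- function(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
                      beta = c(12, 30), gamma = c(30, 50)) {
  b <- rbind(delta, theta, alpha, beta, gamma)
  stopifnot(all(b[, 1] >= 0), all(b[, 1] < b[, 2]), all(b[, 2] <= 50))
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             low = b[, 1], high = b[, 2], row.names = NULL)
}

#' Band power from a spectrum
#'
#' Integral of the density over the half-open band `[low, high)`.
#'
#' @param spectrum a `power_spectrum`.
#' @param low,high band edges in Hz; must lie within the spectrum support.
#' @return band power (uV^2).
#' @export
band_power <- function(spectrum, low, high) {
  stopifnot(inherits(spectrum, "power_spectrum"), low < high)
  support_hi <- max(spectrum$frequency) + spectrum$resolution
  if (low < min(spectrum$frequency) - spectrum$resolution || high > support_hi + 1e-9) {
    stop(sprintf("band [%g, %g) outside spectrum support [%g, %g)",
                 low, high, min(spectrum$frequency), support_hi))
  }
  psd_integral(spectrum, low, high)
}

#' Mean band powers over a recording
#'
#' The EEG is cut into 10-s epochs; each non-artifact epoch's band powers
#' are computed from its own Hamming periodogram and averaged across the
#' recording. Artifact epochs are excluded and the epoch count actually
#' averaged is reported.
#'
#' @param recording a [telemetry_recording()] with an EEG channel.
#' @param bands band table from [eeg_bands()].
#' @param epoch_length averaging epoch length in seconds (default 10).
#' @param grid optional pre-built [segment_epochs()] grid (e.g. already
#'   artifact-flagged); by default a grid is built and flagged with
#'   `artifact`.
#' @param artifact [artifact_params()] used when `grid` is NULL.
#' @return data frame `band`, `low`, `high`, `power` with attribute
#'   `n_epochs` (epochs averaged).
#' @export
recording_band_powers <- function(recording, bands = eeg_bands(),
                                  epoch_length = 10, grid = NULL,
                                  artifact = artifact_params()) {
  eeg <- channel_or_stop(recording, "EEG")
  if (is.null(grid)) {
    grid <- flag_artifacts(recording, segment_epochs(recording, epoch_length),
                           artifact)
  }
  keep <- which(!grid$artifact)
  if (!length(keep)) stop("all epochs flagged artifact; nothing to average")
  per_epoch <- vapply(keep, function(i) {
    sp <- compute_psd(epoch_samples(eeg, grid$epoch_starts[i], grid$epoch_length),
                      eeg$sampling_rate)
    vapply(seq_len(nrow(bands)),
           function(j) band_power(sp, bands$low[j], bands$high[j]), numeric(1))
  }, numeric(nrow(bands)))
  out <- bands
  out$power <- if (is.matrix(per_epoch)) rowMeans(per_epoch) else mean(per_epoch)
  attr(out, "n_epochs") <- length(keep)
  out
}

#' Recording-averaged power spectrum
#'
#' Averages the Hamming periodograms of all non-artifact 30-s epochs,
#' optionally binning the result for reporting.
#'
#' @param recording a [telemetry_recording()].
#' @param epoch_length PSD epoch length in seconds (default 30).
#' @param bin_hz optional reporting bin width in Hz (NULL for native
#'   resolution).
#' @param artifact [artifact_params()] for epoch exclusion.
#' @return a `power_spectrum`.
#' @export
average_psd <- function(recording, epoch_length = 30, bin_hz = NULL,
                        artifact = artifact_params()) {
  eeg <- channel_or_stop(recording, "EEG")
  grid <- flag_artifacts(recording, segment_epochs(recording, epoch_length),
                         artifact)
  keep <- which(!grid$artifact)
  if (!length(keep)) stop("all epochs flagged artifact; nothing to average")
  acc <- NULL
  for (i in keep) {
    sp <- compute_psd(epoch_samples(eeg, grid$epoch_starts[i], grid$epoch_length),
                      eeg$sampling_rate)
    acc <- if (is.null(acc)) sp$power else acc + sp$power
  }
  sp$power <- acc / length(keep)
  if (!is.null(bin_hz)) sp <- bin_psd(sp, bin_hz)
  sp
}
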