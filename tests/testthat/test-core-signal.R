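test_that("epoch segmentation counts epochs and rejects short recordings", {
  expect_equal(length(segment_epochs(duration_stub(72 * 3600), 30)$epoch_starts), 8640)
  expect_equal(length(segment_epochs(duration_stub(72 * 3600), 10)$epoch_starts), 25920)
  expect_error(segment_epochs(duration_stub(25), 30), "too short")
  # trailing partial epoch discarded
  g <- segment_epochs(duration_stub(95), 30)
  expect_equal(g$epoch_starts, c(0, 30, 60))
  expect_false(any(g$artifact))
})

test_that("artifact flagging applies amplitude limits per epoch", {
  fs <- 500
  eeg <- boundary_trace(250, n_total = 3 * 30 * fs, at = c(1000, 2000))
  rec <- telemetry_recording(eeg)
  g <- flag_artifacts(rec, segment_epochs(rec, 30))
  expect_equal(g$artifact, c(TRUE, FALSE, FALSE))  # 0.25 mV excursion in epoch 1

  # flat zero EEG never flagged; sub-limit EEG and EMG not flagged
  rec2 <- telemetry_recording(boundary_trace(190, n_total = 30 * fs),
                              emg = boundary_trace(900, n_total = 30 * fs))
  g2 <- flag_artifacts(rec2, segment_epochs(rec2, 30))
  expect_false(any(g2$artifact))

  # EMG over its own 1 mV limit trips the flag even with quiet EEG
  rec3 <- telemetry_recording(numeric(30 * fs),
                              emg = boundary_trace(1100, n_total = 30 * fs))
  expect_true(all(flag_artifacts(rec3, segment_epochs(rec3, 30))$artifact))

  # missing EMG channel just skips the EMG rule
  rec4 <- telemetry_recording(numeric(30 * fs))
  expect_false(any(flag_artifacts(rec4, segment_epochs(rec4, 30))$artifact))
})

test_that("raising the EEG limit never increases flagged epochs", {
  fs <- 500
  set.seed(11)
  rec <- telemetry_recording(rnorm(fs * 300, sd = 80))
  grid <- segment_epochs(rec, 30)
  counts <- vapply(c(0.15, 0.2, 0.25, 0.3), function(lim) {
    sum(flag_artifacts(rec, grid, artifact_params(eeg_limit_mV = lim))$artifact)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("PSD satisfies Parseval and localizes sinusoids", {
  fs <- 500
  # all-zero epoch -> zero power
  expect_true(all(compute_psd(numeric(fs * 30), fs)$power == 0))
  # Parseval on seeded white noise over the full one-sided spectrum
  set.seed(1)
  x <- rnorm(fs * 30)
  sp <- compute_psd(x, fs, fmax = Inf)
  expect_lt(abs(psd_integral(sp) / var(x) - 1), 0.01)
  # pure 2 Hz sinusoid: total a^2/2, >=95% within 1.5-2.5 Hz
  a <- 50
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  s2 <- compute_psd(a * sin(2 * pi * 2 * t), fs)
  expect_lt(abs(psd_integral(s2) / (a^2 / 2) - 1), 0.01)
  expect_gte(psd_integral(s2, 1.5, 2.5) / psd_integral(s2), 0.95)
  # non-finite input names the first offending index
  bad <- x; bad[17] <- NA
  expect_error(compute_psd(bad, fs), "index 17")
})

test_that("binning conserves power and respects the reporting grid", {
  fs <- 500
  set.seed(5)
  sp <- compute_psd(rnorm(fs * 30), fs)
  b <- bin_psd(sp, 2)
  expect_equal(length(b$frequency), 25)
  expect_equal(b$frequency[1], 1)
  expect_lt(abs(psd_integral(b) / psd_integral(sp, 0, 50) - 1), 0.01)
  # flat density stays flat at any bin width
  flat <- structure(list(frequency = seq(0, 50, by = 1 / 30),
                         power = rep(1, 1501), resolution = 1 / 30),
                    class = "power_spectrum")
  for (w in c(1, 2, 5)) expect_true(all(abs(bin_psd(flat, w)$power - 1) < 1e-12))
})

test_that("band powers partition the spectrum and scale quadratically", {
  fs <- 500
  set.seed(6)
  x <- rnorm(fs * 30, sd = 30)
  sp <- compute_psd(x, fs)
  bands <- eeg_bands()
  per_band <- vapply(seq_len(nrow(bands)), function(i) {
    band_power(sp, bands$low[i], bands$high[i])
  }, numeric(1))
  expect_equal(sum(per_band), psd_integral(sp, 0.5, 50), tolerance = 1e-10)
  # zero spectrum -> zero in every band
  z <- compute_psd(numeric(fs * 30), fs)
  expect_true(all(vapply(seq_len(nrow(bands)), function(i) {
    band_power(z, bands$low[i], bands$high[i])
  }, numeric(1)) == 0))
  # 6 Hz sinusoid lands in theta
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  s6 <- compute_psd(40 * sin(2 * pi * 6 * t), fs)
  expect_gte(band_power(s6, 4, 8) / psd_integral(s6, 0.5, 50), 0.95)
  # c * signal -> c^2 * power
  sp2 <- compute_psd(2 * x, fs)
  expect_equal(psd_integral(sp2), 4 * psd_integral(sp), tolerance = 1e-10)
  expect_error(band_power(sp, 40, 60), "outside")
})

test_that("recording band powers average non-artifact 10-s epochs", {
  fs <- 500
  set.seed(7)
  rec <- telemetry_recording(rnorm(fs * 120, sd = 10))
  bp <- recording_band_powers(rec)
  expect_equal(attr(bp, "n_epochs"), 12)
  # flagging half the epochs averages over the other half only
  grid <- segment_epochs(rec, 10)
  grid$artifact[seq(1, 12, by = 2)] <- TRUE
  bp_half <- recording_band_powers(rec, grid = grid)
  expect_equal(attr(bp_half, "n_epochs"), 6)
  eeg <- rec$channels$EEG
  manual <- mean(vapply(grid$epoch_starts[!grid$artifact], function(s) {
    band_power(compute_psd(eeg$samples[(s * fs + 1):((s + 10) * fs)], fs), 0.5, 4)
  }, numeric(1)))
  expect_equal(bp_half$power[bp_half$band == "delta"], manual, tolerance = 1e-12)
  # doubled amplitude -> every band x4
  rec2 <- telemetry_recording(2 * rec$channels$EEG$samples)
  expect_equal(recording_band_powers(rec2)$power, 4 * bp$power, tolerance = 1e-10)
  # all-artifact is an explicit error
  grid$artifact[] <- TRUE
  expect_error(recording_band_powers(rec, grid = grid), "artifact")
})

test_that("per-epoch band powers show chi-square-like sampling variability", {
  fs <- 500
  set.seed(3)
  rec <- telemetry_recording(rnorm(fs * 600, sd = 10))
  eeg <- rec$channels$EEG
  grid <- segment_epochs(rec, 10)
  cv_of <- function(lo, hi) {
    p <- vapply(grid$epoch_starts, function(s) {
      band_power(compute_psd(eeg$samples[(s * fs + 1):((s + 10) * fs)], fs), lo, hi)
    }, numeric(1))
    sd(p) / mean(p)
  }
  # CV ~ 1/sqrt(m) for a band of m periodogram bins (within a factor
  # allowing for the window-induced bin correlation)
  m_delta <- 3.5 / 0.1
  m_beta <- 18 / 0.1
  expect_gt(cv_of(0.5, 4), 0.7 / sqrt(m_delta))
  expect_lt(cv_of(0.5, 4), 2.0 / sqrt(m_delta))
  expect_gt(cv_of(12, 30), 0.7 / sqrt(m_beta))
  expect_lt(cv_of(12, 30), 2.0 / sqrt(m_beta))
})

test_that("CSV round trip preserves the recording", {
  fs <- 500
  set.seed(8)
  rec <- telemetry_recording(rnorm(fs * 20), emg = rnorm(fs * 20),
                             activity = runif(200 * 20), fs_activity = 200)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path)
  expect_equal(back$channels$EEG$samples, rec$channels$EEG$samples)
  expect_equal(back$channels$EEG$sampling_rate, fs, tolerance = 1e-6)
  expect_equal(back$channels$EMG$samples, rec$channels$EMG$samples)
})
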