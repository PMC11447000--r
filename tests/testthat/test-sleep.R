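feat_row <- function(delta, tdr, emg, act) {
  data.frame(delta_ratio = delta, theta_delta_ratio = tdr,
             emg_ratio = emg, activity = act)
}

test_that("stage probabilities match hand-computed membership averages", {
  # strong delta, weak theta, quiet EMG, no movement -> SWS
  p1 <- stage_probabilities(feat_row(2, 0.5, 0.3, 0))
  expect_equal(as.numeric(p1), c(0, 5 / 24, 14 / 24, 5 / 24),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(colnames(p1)[which.max(p1)], "SWS")
  expect_equal(sum(p1), 1)

  # weak delta, dominant theta, atonia -> paradoxical
  p2 <- stage_probabilities(feat_row(0.4, 4, 0.5, 0))
  expect_equal(as.numeric(p2), c(0, 5 / 24, 5 / 24, 14 / 24),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(colnames(p2)[which.max(p2)], "PARADOXICAL")

  # features at the membership midpoints -> the three non-active stages tie
  pm <- stage_probabilities(feat_row(0.75, 2.15, 1.7, 0))
  expect_equal(as.numeric(pm), c(0, 1, 1, 1) / 3, tolerance = 1e-12,
               ignore_attr = TRUE)
  cls <- classify_epochs(pm, feat_row(0.75, 2.15, 1.7, 0))
  expect_equal(as.character(cls$stage), "WAKE")  # documented tie order

  # undefined theta:delta contributes a uniform evidence vector
  pu <- stage_probabilities(feat_row(2, NA, 0.3, 0))
  expect_equal(sum(pu), 1)
  expect_equal(colnames(pu)[which.max(pu)], "SWS")
})

test_that("membership ramps saturate exactly at the printed anchors", {
  sws_at <- function(d) stage_probabilities(feat_row(d, 0.5, 0.3, 0))[1, "SWS"]
  expect_equal(sws_at(1), sws_at(5))     # saturated at delta ratio 1
  expect_equal(sws_at(0.5), sws_at(0.1)) # floor at 0.5
  expect_lt(sws_at(0.5), sws_at(1))
  par_at <- function(r) stage_probabilities(feat_row(0.4, r, 0.5, 0))[1, "PARADOXICAL"]
  expect_equal(par_at(3), par_at(10))    # saturated at theta:delta 3
  expect_equal(par_at(1.3), par_at(0.2))
  wake_at <- function(e) stage_probabilities(feat_row(0.75, 0.5, e, 0))[1, "WAKE"]
  expect_equal(wake_at(2.4), wake_at(3)) # saturated at EMG ratio 2.4
  expect_equal(wake_at(1), wake_at(0.2))
})

test_that("active-wake override fires on activity or extreme EMG", {
  p <- stage_probabilities(feat_row(2, 0.5, 0.3, 0.5))
  cls <- classify_epochs(p, feat_row(2, 0.5, 0.3, 0.5))
  expect_equal(as.character(cls$stage), "ACTIVE_WAKE")
  expect_true(cls$override)
  # EMG ratio 3.7 >= 1.5 x 2.4 forces active wake with zero activity
  f2 <- feat_row(2, 0.5, 3.7, 0)
  cls2 <- classify_epochs(stage_probabilities(f2), f2)
  expect_equal(as.character(cls2$stage), "ACTIVE_WAKE")
  # just under the 1.5x rule: no override
  f3 <- feat_row(2, 0.5, 3.59, 0)
  cls3 <- classify_epochs(stage_probabilities(f3), f3)
  expect_false(cls3$override)
  # activity exactly at 0.1 does not fire (strict >)
  f4 <- feat_row(2, 0.5, 0.3, 0.1)
  expect_false(classify_epochs(stage_probabilities(f4), f4)$override)
  # no override: argmax wins
  f5 <- feat_row(2, 0.5, 0.5, 0)
  expect_equal(as.character(classify_epochs(stage_probabilities(f5), f5)$stage), "SWS")
})

test_that("probabilities are monotone in their discriminating features", {
  sws <- vapply(seq(0.3, 2, by = 0.1), function(d) {
    stage_probabilities(feat_row(d, 1, 0.8, 0))[1, "SWS"]
  }, numeric(1))
  expect_true(all(diff(sws) >= -1e-12))
  wake <- vapply(seq(0.2, 3.5, by = 0.1), function(e) {
    stage_probabilities(feat_row(0.8, 1, e, 0))[1, "WAKE"]
  }, numeric(1))
  expect_true(all(diff(wake) >= -1e-12))
})

test_that("stage features self-normalize and flag degenerate inputs", {
  fs <- 500
  set.seed(31)
  rec <- telemetry_recording(rnorm(fs * 100, sd = 30), emg = rnorm(fs * 100, sd = 20),
                             activity = runif(200 * 100, 0, 0.05), fs_activity = 200)
  f <- compute_stage_features(rec)
  expect_equal(mean(f$delta_ratio), 1, tolerance = 1e-9)
  expect_equal(mean(f$emg_ratio), 1, tolerance = 1e-9)
  # epoch with doubled EEG amplitude -> delta ratio ~4x the others
  # (amplitudes kept well under the 0.2 mV artifact limit)
  x <- rnorm(fs * 100, sd = 15)
  x[(3 * 10 * fs + 1):(4 * 10 * fs)] <- 2 * x[(3 * 10 * fs + 1):(4 * 10 * fs)]
  rec2 <- telemetry_recording(x, emg = rnorm(fs * 100, sd = 20),
                              activity = runif(200 * 100, 0, 0.05),
                              fs_activity = 200)
  f2 <- compute_stage_features(rec2)
  expect_equal(f2$delta_ratio[4] / mean(f2$delta_ratio[-4]), 4, tolerance = 0.7)
  # zero EMG -> undefined ratio
  rec3 <- telemetry_recording(rnorm(fs * 100, sd = 30), emg = numeric(fs * 100),
                              activity = numeric(200 * 100), fs_activity = 200)
  expect_true(all(is.na(compute_stage_features(rec3)$emg_ratio)))
  # missing channels are named
  expect_error(compute_stage_features(telemetry_recording(rnorm(fs * 100))), "EMG")
})

test_that("permuting epochs permutes the hypnogram identically", {
  set.seed(32)
  f <- feat_row(runif(20, 0.2, 2), runif(20, 0.5, 4), runif(20, 0.2, 3),
                sample(c(0, 0.5), 20, replace = TRUE))
  perm <- sample(20)
  cls <- classify_epochs(stage_probabilities(f), f)
  cls_p <- classify_epochs(stage_probabilities(f[perm, ]), f[perm, ])
  expect_equal(as.character(cls_p$stage), as.character(cls$stage)[perm])
})

test_that("hypnogram summaries report percentages over scored epochs", {
  mk_hyp <- function(stages) {
    structure(data.frame(stage = factor(stages,
                                        levels = c("ACTIVE_WAKE", "WAKE", "SWS",
                                                   "PARADOXICAL", "ARTIFACT"))),
              epoch_length = 10, class = c("hypnogram", "data.frame"))
  }
  s <- summarize_hypnogram(mk_hyp(rep("WAKE", 50)))
  expect_equal(unname(s$percent["WAKE"]), 100)
  s2 <- summarize_hypnogram(mk_hyp(rep(c("ACTIVE_WAKE", "WAKE", "SWS",
                                         "PARADOXICAL"), each = 2160)))
  expect_equal(unname(s2$percent), rep(25, 4))
  expect_equal(sum(s2$percent), 100, tolerance = 0.01)
  expect_equal(s2$scored_hours, 24)
  s3 <- summarize_hypnogram(mk_hyp(c(rep("SWS", 9), "ARTIFACT")))
  expect_equal(unname(s3$percent["SWS"]), 100)
  expect_equal(s3$artifact_fraction, 0.1)
  expect_error(summarize_hypnogram(mk_hyp(rep("ARTIFACT", 5))), "no scored")
})

test_that("staging recovers a known stage sequence", {
  seq_ <- generate_stage_sequence(120, seed = 33)
  g <- generate_sleep_recording(seq_, seed = 34)
  hyp <- stage_recording(g$recording)
  scored <- as.character(hyp$stage) != "ARTIFACT"
  agree <- mean(as.character(hyp$stage)[scored] == g$stages$stage[scored])
  expect_gte(agree, 0.9)
  # probability rows sum to one on scored epochs
  pr <- as.matrix(hyp[scored, c("p_active_wake", "p_wake", "p_sws", "p_paradoxical")])
  expect_true(all(abs(rowSums(pr) - 1) < 1e-9))
})
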