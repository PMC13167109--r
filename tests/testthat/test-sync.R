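# Clock synchronisation: annotation matching, ECG refinement, and the
# median-offset computation with its quality-control thresholds.

test_that("match_annotations returns per-id time differences", {
  a <- annotation_set(c(10, 20, 30, 40, 50), letters[1:5])
  expect_equal(unname(match_annotations(a, a)), rep(0, 5))
  b <- annotation_set(a$times + 2.5, a$ids)
  expect_equal(unname(match_annotations(a, b)), rep(2.5, 5))
  # ids matched by name, not order
  b2 <- annotation_set(c(12.5, 22.5, 32.5, 42.5), c("b", "a", "e", "c"))
  expect_error(match_annotations(a, b2), "insufficient")
})

test_that("annotation differences recover the injected jitter SD", {
  p <- gen_ecg_pair(300, offset = 1, jitter_sd = 0.105, seed = 4)
  d <- match_annotations(p$annotations_vitals, p$annotations_eeg)
  expect_lt(abs(sd(d) - 0.105), 0.035)
})

test_that("ECG refinement recovers the offset within one vitals sample", {
  for (seed in 1:3) {
    p <- gen_ecg_pair(120, offset = 2.5, seed = seed)
    d <- match_annotations(p$annotations_vitals, p$annotations_eeg)
    tv <- p$annotations_vitals$times[match(names(d), p$annotations_vitals$ids)]
    te <- p$annotations_eeg$times[match(names(d), p$annotations_eeg$ids)]
    refined <- refine_with_ecg(p$ecg_vitals, p$ecg_eeg, tv, te)
    expect_lt(abs(median(refined) - 2.5), 1 / 250)
    # per-annotation refinement is far tighter than the raw annotation jitter
    expect_lt(sd(refined), sd(d))
  }
})

test_that("refinement against a brute-force cross-correlation oracle", {
  p <- gen_ecg_pair(90, offset = 1.2, n_annotations = 6, jitter_sd = 0.02,
                    seed = 9)
  d <- match_annotations(p$annotations_vitals, p$annotations_eeg)
  tv <- p$annotations_vitals$times[match(names(d), p$annotations_vitals$ids)]
  te <- p$annotations_eeg$times[match(names(d), p$annotations_eeg$ids)]
  refined <- refine_with_ecg(p$ecg_vitals, p$ecg_eeg, tv, te)
  # oracle: integer-lag scan of the correlation for the first annotation
  fs <- 250
  rel <- seq(-10, 10, by = 1 / fs)
  wa <- approx(ts_times(p$ecg_vitals), ts_channel(p$ecg_vitals, 1),
               tv[1] + rel)$y
  wb <- approx(ts_times(p$ecg_eeg), ts_channel(p$ecg_eeg, 1),
               te[1] + rel)$y
  lags <- seq(-2 * fs, 2 * fs)
  cors <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(wa[seq_len(length(wa) - k)],
                           wb[seq_len(length(wa) - k) + k])
    else stats::cor(wa[(1 - k):length(wa)], wb[seq_len(length(wa) + k)])
  }, 0)
  oracle <- (te[1] - tv[1]) - lags[which.max(cors)] / fs
  expect_lt(abs(refined[1] - oracle), 1 / fs)
})

test_that("flat ECG windows are skipped with a log entry", {
  p <- gen_ecg_pair(120, offset = 0.5, n_annotations = 8, seed = 6)
  d <- match_annotations(p$annotations_vitals, p$annotations_eeg)
  tv <- p$annotations_vitals$times[match(names(d), p$annotations_vitals$ids)]
  te <- p$annotations_eeg$times[match(names(d), p$annotations_eeg$ids)]
  # flatten the vitals ECG around the third annotation
  x <- p$ecg_vitals$samples
  tt <- ts_times(p$ecg_vitals)
  x[tt > tv[3] - 10.5 & tt < tv[3] + 10.5] <- 0
  pv <- time_series(x, p$ecg_vitals$fs, labels = "ECG")
  refined <- suppressMessages(refine_with_ecg(pv, p$ecg_eeg, tv, te))
  expect_length(refined, length(tv) - 1)
  expect_equal(attr(refined, "skipped"), 3L)
})

test_that("compute_sync takes the median and applies the QC thresholds", {
  expect_equal(compute_sync(c(2.49, 2.50, 2.51, 2.50, 2.50))$offset, 2.50)
  big <- compute_sync(c(0, 1, 2, 3, 4))          # SD ~ 1.58 s
  expect_true(big$excluded)
  expect_match(big$reason, "annotation")
  ok <- compute_sync(rnorm(10, 2.5, 0.3), rnorm(10, 2.5, 0.03))
  expect_false(ok$excluded)
  bad_ecg <- compute_sync(rnorm(10, 2.5, 0.3), rnorm(10, 2.5, 0.3))
  expect_true(bad_ecg$excluded)
  expect_match(bad_ecg$reason, "ECG")
  expect_error(compute_sync(c(1, 2, 3)), "at least 5")
})

test_that("synchronising twice is idempotent", {
  rec <- gen_recording(duration = 90, offset = 2.5, fs_eeg = 250,
                       rspec = resp_spec(apnoea_rate = 0), seed = 8)
  s1 <- sync_recording(rec)
  expect_false(s1$sync$excluded)
  expect_equal(s1$sync$offset, 2.5, tolerance = 0.004)
  s2 <- sync_recording(s1$recording)
  expect_lt(abs(s2$sync$offset), 0.004)
})
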