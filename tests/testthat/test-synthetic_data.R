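# Generators: ground truth returned exactly, determinism under seed, and the
# injected structure matches its analytic description.

test_that("respiration generator produces the requested breaths and apnoeas", {
  r <- gen_respiration(resp_spec(rate = 60, rate_sd = 0, apnoea_rate = 0),
                       duration = 120, fs = 62.5, seed = 1)
  expect_equal(length(r$breath_times), 120)  # 1 Hz x 120 s
  expect_equal(nrow(r$apnoeas), 0)

  r2 <- gen_respiration(resp_spec(apnoea_rate = 2), duration = 3600,
                        fs = 62.5, seed = 2)
  expect_equal(nrow(r2$apnoeas), 2)
  expect_true(all(r2$apnoeas$end - r2$apnoeas$start >= 15))
  # apnoea gaps contain no breath onsets
  for (k in seq_len(nrow(r2$apnoeas))) {
    expect_false(any(r2$breath_times > r2$apnoeas$start[k] &
                       r2$breath_times < r2$apnoeas$end[k]))
  }

  a <- gen_respiration(resp_spec(), duration = 200, fs = 62.5, seed = 7)
  b <- gen_respiration(resp_spec(), duration = 200, fs = 62.5, seed = 7)
  expect_identical(a$ip$samples, b$ip$samples)
  expect_identical(a$breath_times, b$breath_times)

  expect_error(
    gen_respiration(resp_spec(apnoea_rate = 120), duration = 400, fs = 62.5),
    "overlapping"
  )
  expect_error(resp_spec(apnoea_duration = 10), ">= 15")
})

test_that("phase function is linear within cycles and NA during apnoea", {
  r <- gen_respiration(resp_spec(rate = 60, rate_sd = 0, apnoea_rate = 0),
                       duration = 120, fs = 62.5, seed = 1)
  expect_equal(r$phase_fn(0.5), pi, tolerance = 1e-9)
  expect_equal(r$phase_fn(10.25), pi / 2, tolerance = 1e-9)
  r2 <- gen_respiration(resp_spec(apnoea_rate = 4), duration = 3600,
                        fs = 62.5, seed = 3)
  mid <- rowMeans(r2$apnoeas)
  expect_true(all(is.na(r2$phase_fn(mid))))
})

test_that("injected coupling has the stated modulation structure", {
  dur <- 240
  resp <- quiet_resp(dur, seed = 3)
  tt <- seq(0, dur - 1 / 50, by = 1 / 50)

  # m = 0: no phase preference of the carrier envelope
  eeg0 <- gen_coupled_eeg(resp$phase_fn, coupling_spec(m = 0, channels = "FCz"),
                          dur, fs = 50, labels = "FCz", seed = 11)
  env0 <- ts_channel(envelope(eeg0, 6, 4), 1)
  ph <- resp$phase_fn(tt)
  ok <- !is.na(ph)
  resultant <- Mod(sum(env0[ok] * exp(1i * ph[ok]))) / sum(env0[ok])
  expect_lt(resultant, 0.05)

  # m = 0.8: modulator peak-to-trough ratio (1+m)/(1-m) = 9
  modv <- 1 + 0.8 * cos(ph[ok])
  expect_equal(max(modv) / min(modv), 9, tolerance = 0.05)

  # m = 0.8 channel shows a clear phase preference; uncoupled channel none
  eeg1 <- gen_coupled_eeg(resp$phase_fn,
                          coupling_spec(m = 0.8, channels = "FCz"),
                          dur, fs = 50, labels = c("FCz", "Oz"), seed = 12)
  env1 <- ts_channel(envelope(eeg1, 6, 4), "FCz")
  res1 <- Mod(sum(env1[ok] * exp(1i * ph[ok]))) / sum(env1[ok])
  expect_gt(res1, 0.1)
  envoz <- ts_channel(envelope(eeg1, 6, 4), "Oz")
  expect_lt(Mod(sum(envoz[ok] * exp(1i * ph[ok]))) / sum(envoz[ok]), 0.05)
})

test_that("the envelope lag equals the injected tau (brute-force xcorr)", {
  dur <- 300
  fs <- 50
  resp <- quiet_resp(dur, seed = 5)
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  peak_lag <- function(tau, seed) {
    cs <- coupling_spec(band = c(4, 8), m = 0.6, tau = tau, channels = "FCz")
    eeg <- gen_coupled_eeg(resp$phase_fn, cs, dur, fs = fs, labels = "FCz",
                           seed = seed)
    env <- ts_channel(envelope(eeg, 6, 4), 1)
    modv <- 1 + 0.6 * cos(resp$phase_fn(tt))  # lag-free modulator
    modv[is.na(modv)] <- 1
    lags <- seq(-1, 1, by = 1 / fs)
    cors <- vapply(lags, function(l) {
      sh <- round(l * fs)
      if (sh >= 0) stats::cor(env[seq_len(length(env) - sh)],
                              modv[seq_len(length(env) - sh) + sh])
      else stats::cor(env[(1 - sh):length(env)],
                      modv[seq_len(length(env) + sh)])
    }, 0)
    lags[which.max(cors)]
  }
  expect_equal(peak_lag(0.3, 21), 0.3, tolerance = 0.08)
  expect_equal(peak_lag(-0.3, 22), -0.3, tolerance = 0.08)
})

test_that("dual-device ECG pair carries the injected offset and jitter", {
  p0 <- gen_ecg_pair(90, offset = 0, seed = 1)
  # common 250 Hz grid, brute-force normalised cross-correlation
  tt <- seq(10, 80, by = 1 / 250)
  a <- approx(ts_times(p0$ecg_vitals), ts_channel(p0$ecg_vitals, 1), tt)$y
  b <- approx(ts_times(p0$ecg_eeg), ts_channel(p0$ecg_eeg, 1), tt)$y
  cc <- stats::ccf(a, b, lag.max = 250, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  p <- gen_ecg_pair(300, offset = 2.5, jitter_sd = 0.105, seed = 2)
  expect_equal(p$offset, 2.5)
  d <- p$annotations_eeg$times[match(p$annotations_vitals$ids,
                                     p$annotations_eeg$ids)] -
    p$annotations_vitals$times
  expect_equal(mean(d), 2.5, tolerance = 0.06)
  expect_lt(abs(sd(d) - 0.105), 0.035)  # n = 30 chi spread
})

test_that("cohort generator matches the study shape and injected slope", {
  co <- gen_cohort(seed = 1)
  expect_equal(nrow(co), 104)
  expect_equal(length(unique(co$infant_id)), 68)
  expect_true(all(co$apnoea_rate >= 0))
  expect_true(all(co$pma_weeks >= 28 & co$pma_weeks <= 42))
  expect_true(all(co$data_length_hours <= 24))
  expect_identical(co, gen_cohort(seed = 1))

  null_r <- cor(gen_cohort(slope = 0, seed = 2)$pac,
                gen_cohort(slope = 0, seed = 2)$apnoea_rate)
  expect_lt(abs(null_r), 0.2)
  neg <- suppressWarnings(gen_cohort(slope = -2.5, seed = 3))
  expect_lt(cor(neg$pac, neg$apnoea_rate), 0)
})
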