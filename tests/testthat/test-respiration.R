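# Breath detection, long-IBI classification, apnoea rate and the phase
# function.

test_that("IP filter preserves respiration and attenuates cardiac artifact", {
  fs <- 62.5
  tt <- seq(0, 120 - 1 / fs, by = 1 / fs)
  tone <- function(f) sin(2 * pi * f * tt)
  amp_at <- function(x, f) {
    sp <- Mod(fft(x))
    sp[round(f * length(x) / fs) + 1]
  }
  y <- ts_channel(filter_ip(time_series(tone(1), fs)), 1)
  expect_gt(amp_at(y, 1) / amp_at(tone(1), 1), 0.95)  # < 5% loss at 1 Hz

  mix <- tone(1) + tone(2.2)
  ymix <- ts_channel(filter_ip(time_series(mix, fs)), 1)
  atten_db <- 20 * log10(amp_at(mix, 2.2) / amp_at(ymix, 2.2))
  expect_gt(atten_db, 20)

  # zero phase: impulse response symmetric about the impulse
  imp <- numeric(120 * fs)
  imp[3750] <- 1
  h <- ts_channel(filter_ip(time_series(imp, fs)), 1)
  k <- 200
  expect_equal(h[3750 + 1:k], h[3750 - 1:k], tolerance = 1e-8)

  expect_error(filter_ip(time_series(rnorm(100), fs)), "too short")
})

test_that("adaptive threshold detects every cycle of a clean sinusoid", {
  fs <- 62.5
  x <- sin(2 * pi * seq(0, 60 - 1 / fs, by = 1 / fs))
  rec <- detect_breaths(time_series(x, fs))
  expect_equal(length(rec$onsets), 60)
  # all full IBIs are 1 s to within one sample
  expect_true(all(abs(rec$ibis[-1] - 1) <= 1 / fs + 1e-9))

  flat <- detect_breaths(time_series(numeric(60 * fs), fs))
  expect_equal(length(flat$onsets), 0)
  expect_true(flat$flagged)
})

test_that("detection is invariant to signal scaling and adapts to amplitude", {
  r <- quiet_resp(180, seed = 2)
  ipf <- filter_ip(r$ip)
  rec1 <- detect_breaths(ipf)
  ipf5 <- time_series(5 * ipf$samples, ipf$fs, labels = "IP")
  expect_identical(detect_breaths(ipf5)$onsets, rec1$onsets)

  # amplitude halves mid-record; the running-SD threshold follows within
  # 15 breaths and detection continues
  fs <- 62.5
  tt <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * tt) * ifelse(tt < 60, 1, 0.5)
  rec <- detect_breaths(time_series(x, fs))
  late <- rec$onsets[rec$onsets > 75]
  expect_gt(length(late), 40)  # one onset per second after adaptation
})

test_that("detector recovers generator ground truth with high fidelity", {
  r <- quiet_resp(300, seed = 4, noise_sd = 0.1, apnoea_rate = 0)
  rec <- detect_breaths(filter_ip(r$ip))
  tol <- 0.4
  sens <- mean(vapply(r$breath_times,
                      function(t) any(abs(rec$onsets - t) < tol), TRUE))
  fdr <- mean(vapply(rec$onsets,
                     function(t) all(abs(r$breath_times - t) >= tol), TRUE))
  expect_gte(sens, 0.95)
  expect_lte(fdr, 0.05)
})

test_that("long IBIs are classified and shallow breathing is discarded", {
  r <- gen_respiration(resp_spec(apnoea_rate = 4), duration = 1800,
                       fs = 62.5, seed = 5)
  rec <- classify_long_ibis(detect_breaths(filter_ip(r$ip)), r$ip)
  expect_no_na(rec$long_ibis$label)
  # every true apnoea overlaps an apnoea-labelled interval
  apn <- rec$long_ibis[rec$long_ibis$label == "apnoea", ]
  for (k in seq_len(nrow(r$apnoeas))) {
    expect_true(any(apn$start < r$apnoeas$end[k] &
                      apn$end > r$apnoeas$start[k]))
  }

  # shallow breathing at 20% amplitude inside a long gap -> noise-or-shallow
  rs <- gen_respiration(resp_spec(rate = 60, rate_sd = 0, apnoea_rate = 0),
                        300, 62.5, seed = 9)
  x <- ts_channel(rs$ip, 1)
  tt <- ts_times(rs$ip)
  x[tt >= 100 & tt < 130] <- 0.2 * x[tt >= 100 & tt < 130]
  ip2 <- time_series(x, 62.5, labels = "IP")
  rec2 <- classify_long_ibis(detect_breaths(filter_ip(ip2)), ip2)
  expect_true(nrow(rec2$long_ibis) >= 1)
  expect_true(all(rec2$long_ibis$label == "noise-or-shallow"))
})

test_that("IBIs below 15 s are never passed to the classifier", {
  rec <- breath_record(c(0, cumsum(c(rep(1, 10), 14.9, rep(1, 10)))), fs = 62.5)
  expect_equal(nrow(rec$long_ibis), 0)
  rec2 <- breath_record(c(0, cumsum(c(rep(1, 10), 15.0, rep(1, 10)))),
                        fs = 62.5)
  expect_equal(nrow(rec2$long_ibis), 1)
})

test_that("apnoea rate is events per analysed hour", {
  rec <- breath_record(seq(0, 12 * 3600, by = 2), fs = 62.5)
  # craft a record with 6 labelled apnoeas in 12 h
  rec$long_ibis <- data.frame(index = 1:6, start = 1:6, end = 2:7,
                              ibi = rep(16, 6), label = rep("apnoea", 6))
  expect_equal(apnoea_rate(rec, 12), 0.5)
  rec$long_ibis <- rec$long_ibis[0, ]
  expect_equal(apnoea_rate(rec, 12), 0)
  expect_error(apnoea_rate(rec, 25), "24")

  # generator truth at 2/h over 6 h: estimate within the Poisson 95% band
  r <- gen_respiration(resp_spec(apnoea_rate = 2), duration = 6 * 3600,
                       fs = 62.5, seed = 6)
  recg <- classify_long_ibis(detect_breaths(filter_ip(r$ip)), r$ip)
  est <- apnoea_rate(recg)
  band <- qpois(c(0.025, 0.975), lambda = 2 * 6) / 6
  expect_gte(est, band[1])
  expect_lte(est, band[2])
})

test_that("phase function is linear, 50-point grid, excludes long IBIs", {
  rec <- breath_record(c(0, 1, 2, 3, 4, 5, 25, 26, 27, 28, 29, 30, 31),
                       fs = 62.5)
  rec$long_ibis$label <- "noise-or-shallow"
  pf <- phase_function(rec)
  expect_equal(pf$fn(0.5), pi)
  expect_equal(pf$fn(2.25), pi / 2)
  expect_true(is.na(pf$fn(10)))          # inside the discarded interval
  expect_false(any(pf$cycles$onset == 5))  # long IBI cycle dropped

  # 50-point grid on 1-s cycles: spacing 0.02 s
  ts <- time_series(seq(0, 40, by = 1 / 62.5), fs = 62.5)
  grid <- pf$resample(ts, 1, n_points = 50)
  expect_equal(ncol(grid), 50)
  # the resampled values of t itself advance by dur/50 = 0.02 s
  expect_equal(diff(grid[1, 1:2]), 0.02, tolerance = 1e-6)
})
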