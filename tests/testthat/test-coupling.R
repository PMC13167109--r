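# Epoching, rejection, envelope extraction, cross-frequency coherence,
# cycle-resolved PAC, breath-locked maps and the phase-slope index.

test_that("epoching yields the expected windows and 0.25 Hz resolution", {
  fs_ip <- 62.5
  ip <- time_series(rnorm(60 * fs_ip), fs_ip, labels = "IP")
  eeg <- time_series(matrix(rnorm(60 * 50 * 2), ncol = 2), 50,
                     labels = c("FCz", "Cz"))
  ep <- make_epochs(ip, eeg, L = 4, overlap = 0.5)
  expect_equal(ep$n, 29)              # floor((60 - 4)/2) + 1
  expect_equal(ep$delta_f, 0.25)
  expect_identical(ep$eeg_order, seq_len(29))  # pairing preserved
  expect_equal(ncol(ep$ip), 250)

  # epochs with missing samples are excluded at epoching
  ipna <- ip
  ipna$samples[100:150] <- NA
  epna <- make_epochs(ipna, eeg)
  expect_lt(epna$n, 29)
  expect_true(all(epna$rejection_log$rule == "missing-samples"))
})

test_that("rejection rules fire in order and identical epochs survive", {
  fs <- 50
  set.seed(42)
  ip <- time_series(rep(sin(2 * pi * seq(0, 4 - 1 / 62.5, by = 1 / 62.5)), 15),
                    62.5, labels = "IP")
  eeg <- time_series(rnorm(60 * fs), fs, labels = "FCz")
  ep <- make_epochs(ip, eeg)
  # stationary epochs: none rejected by the SD or amplitude rules
  expect_equal(reject_epochs(ep)$n, ep$n)

  # a 20x SD spike triggers the amplitude rule
  eeg2 <- eeg
  eeg2$samples[1000] <- 20 * sd(eeg$samples)
  ep2 <- reject_epochs(make_epochs(ip, eeg2))
  expect_true("amplitude-bound" %in% ep2$rejection_log$rule)

  # an epoch over an apnoea (no breaths) is removed by the breath rule
  r <- gen_respiration(resp_spec(apnoea_rate = 12), 1200, 62.5, seed = 3)
  ipf <- filter_ip(r$ip)
  rec <- detect_breaths(ipf)
  eeg3 <- time_series(rnorm(1200 * fs), fs, labels = "FCz")
  ep3 <- reject_epochs(make_epochs(ipf, eeg3), rec)
  rej <- ep3$rejection_log
  breath_rej <- rej$start[rej$rule == "fewer-than-min-breaths"]
  for (k in seq_len(nrow(r$apnoeas))) {
    expect_true(any(breath_rej < r$apnoeas$end[k] &
                      breath_rej + 4 > r$apnoeas$start[k]))
  }
})

test_that("envelope recovers tone amplitude and AM modulation (closed form)", {
  fs <- 100
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  tone <- time_series(3 * sin(2 * pi * 6 * tt), fs, labels = "FCz")
  env <- ts_channel(envelope(tone, 6, 2), 1)
  core <- env[(5 * fs):(55 * fs)]       # away from the edges
  expect_equal(mean(core), 3, tolerance = 0.02)
  expect_lt(sd(core) / mean(core), 0.02)

  # AM tone: carrier 6 Hz, modulator 0.75 Hz, depth 0.5
  am <- time_series((1 + 0.5 * cos(2 * pi * 0.75 * tt)) *
                      sin(2 * pi * 6 * tt), fs, labels = "FCz")
  env2 <- ts_channel(envelope(am, 6, 5), 1)  # f1 = 5 Hz -> bandwidth 5 Hz
  core2 <- env2[(5 * fs + 1):(53 * fs)]      # 48 s = 36 modulator cycles
  sp <- Mod(fft(core2 - mean(core2))) / length(core2) * 2
  f_axis <- (seq_along(core2) - 1) * fs / length(core2)
  pk <- which.max(sp[f_axis > 0.1 & f_axis < 2])
  expect_equal(f_axis[f_axis > 0.1 & f_axis < 2][pk], 0.75, tolerance = 0.03)
  expect_equal(max(sp[f_axis > 0.1 & f_axis < 2]) / mean(core2), 0.5,
               tolerance = 0.02)

  expect_error(envelope(tone, 49, 4), "Nyquist")
  expect_error(envelope(tone, 1, 4), "Nyquist|outside")
})

test_that("coherency kernel: proportional signals give 1, estimator guards", {
  x <- complex(modulus = runif(32, 0.5, 2), argument = runif(32, 0, 2 * pi))
  expect_equal(Mod(coherency(x, 3 * x)), 1, tolerance = 1e-12)
  expect_error(coherency(x[1], x[1]), "single epoch")

  # null level for independent epochs at N = 64 is ~ sqrt(pi/4)/sqrt(N)
  set.seed(7)
  v <- replicate(400, {
    a <- complex(modulus = 1, argument = runif(64, 0, 2 * pi))
    b <- complex(modulus = 1, argument = runif(64, 0, 2 * pi))
    Mod(coherency(a, b))
  })
  expect_equal(mean(v), sqrt(pi / 4) / sqrt(64), tolerance = 0.05)
})

test_that("pac_coherence validates the f1 grid and epoch count", {
  s <- coupled_setup(seed = 2, duration = 120)
  expect_error(pac_coherence(s$epochs, f1 = 0.3, f2 = 6), "grid")
  one <- s$epochs
  one$starts <- one$starts[1]; one$ip <- one$ip[1, , drop = FALSE]
  one$eeg_order <- 1L; one$n <- 1L
  expect_error(pac_coherence(one, 1, 6), "at least 2")
  cc <- pac_coherence(s$epochs, 1, 6)
  expect_true(is.complex(cc))
  expect_lte(Mod(cc), 1)
})

test_that("spectrum localises injected coupling and respects bounds", {
  s <- coupled_setup(seed = 3, m = 0.6, band = c(4, 8),
                     labels = c("FCz", "Oz"))
  sp <- pac_spectrum(s$epochs, f2_grid = seq(0.5, 12, by = 0.25))
  expect_true(all(sp$coherence >= 0 & sp$coherence <= 1, na.rm = TRUE))
  expect_equal(Mod(sp$coherency), sp$coherence)
  am <- which(sp$coherence[, , "FCz"] == max(sp$coherence[, , "FCz"],
                                             na.rm = TRUE), arr.ind = TRUE)
  f1_hat <- sp$f1_grid[am[1]]
  f2_hat <- sp$f2_grid[am[2]]
  rf <- resp_frequency(s$record, 0.25)
  expect_lte(abs(f1_hat - rf), 0.25)
  # envelope filters with passbands intersecting the carrier band see the
  # modulation, so the argmax may sit up to one bandwidth outside the band
  expect_gte(f2_hat, 4 - f1_hat)
  expect_lte(f2_hat, 8 + f1_hat)
  # uncoupled channel stays near the null bias level
  bias <- sqrt(pi / 4) / sqrt(sp$n_epochs)
  expect_lt(max(sp$coherence[, , "Oz"], na.rm = TRUE), 4 * bias)
})

test_that("band averages are plain means over band cells and mask", {
  res <- fake_coupling_result(
    array(0.3, dim = c(2, 4, 1), dimnames = list(NULL, NULL, "FCz")),
    f1_grid = c(0.75, 1), f2_grid = c(4, 5, 6, 7), channels = "FCz"
  )
  expect_equal(band_average(res, list(theta = c(4, 8)))[1, 1], 0.3)

  res$coherence[] <- c(rep(0.2, 4), rep(0.4, 4))  # f2 cols 1-2: 0.2, 3-4: 0.4
  mask <- array(FALSE, dim = dim(res$coherence))
  mask[, 2:3, 1] <- TRUE   # two cells at 0.2, two at 0.4
  expect_equal(band_average(res, list(theta = c(4, 8)), mask = mask)[1, 1],
               0.3)
  empty <- array(FALSE, dim = dim(res$coherence))
  expect_true(is.na(band_average(res, list(theta = c(4, 8)),
                                 mask = empty)[1, 1]))
})

test_that("cycle-resolved PAC has 50 points and localises a phase gate", {
  s <- coupled_setup(seed = 4, m = 0.8, phi0 = pi / 2, band = c(4, 8),
                     phase_gate = c(0, pi), duration = 300,
                     channels = c("FCz", "Cz"), labels = c("FCz", "Cz"))
  cp <- cycle_pac(s$resp$ip, s$eeg, s$record)
  expect_length(cp$phase_grid, 50)
  expect_true(all(cp$coherence >= 0 & cp$coherence <= 1))
  pooled <- colMeans(cp$coherence)
  expect_lt(cp$phase_grid[which.max(pooled)], pi)

  # uniform coupling: above the null bias at every phase point
  su <- coupled_setup(seed = 5, m = 0.6, band = c(4, 8), duration = 300,
                      channels = c("FCz", "Cz"), labels = c("FCz", "Cz"))
  cpu <- cycle_pac(su$resp$ip, su$eeg, su$record)
  s0 <- coupled_setup(seed = 6, m = 0, band = c(4, 8), duration = 300,
                      channels = c("FCz", "Cz"), labels = c("FCz", "Cz"))
  cp0 <- cycle_pac(s0$resp$ip, s0$eeg, s0$record)
  bias <- sqrt(pi / 4) / sqrt(2 * cpu$n_breaths)
  expect_gt(min(colMeans(cpu$coherence)), 2 * bias)
  expect_lt(max(cp0$coherence), 6 * bias)
})

test_that("breath-locked map is flat at m = 0 and peaks at phi0 otherwise", {
  s0 <- coupled_setup(seed = 7, m = 0, band = c(0.5, 4), duration = 600,
                      channels = c("FCz", "Cz"), labels = c("FCz", "Cz"))
  tf0 <- breath_locked_tf(s0$eeg, s0$record, f_grid = seq(1, 10, by = 1))
  tr0 <- tf0$band_traces["delta", ]
  expect_lt(diff(range(tr0)) / mean(tr0), 0.10)

  s1 <- coupled_setup(seed = 8, m = 0.5, phi0 = 0, band = c(0.5, 4),
                      duration = 600, channels = c("FCz", "Cz"),
                      labels = c("FCz", "Cz"))
  tf1 <- breath_locked_tf(s1$eeg, s1$record, f_grid = seq(1, 10, by = 1))
  tr1 <- tf1$band_traces["delta", ]
  pk <- tf1$phase_grid[which.max(tr1)]
  # peak at inspiration onset (phase 0), allowing wrap-around
  expect_lt(min(pk, 2 * pi - pk), pi / 2)
  expect_equal(tf1$f_grid, seq(1, 10, by = 1))
})

test_that("phase-slope index: window arithmetic, sign flip, zero-lag null", {
  s <- coupled_setup(seed = 9, m = 0.6, tau = 0.3, band = c(2, 6),
                     duration = 300, rate = 54)
  sp <- pac_spectrum(s$epochs, f2_grid = seq(2, 6, by = 0.5))
  psi <- phase_slope_index(sp, beta = 1)
  expect_equal(psi$beta, 1)
  # rows whose +/- beta/2 window exceeds the f1 grid are missing
  expect_true(all(is.na(psi$psi[1, , ])))                 # f1 = 0.25
  expect_true(all(is.na(psi$psi[length(sp$f1_grid), , ]))) # f1 = 2
  i <- which(sp$f1_grid == 1)
  expect_false(anyNA(psi$psi[i, , ]))
  expect_error(phase_slope_index(sp, beta = 0.5), "4 times")

  # envelope leading (tau > 0) gives positive psi; trailing gives negative
  val_pos <- mean(psi$psi[i, , 1], na.rm = TRUE)
  s2 <- coupled_setup(seed = 9, m = 0.6, tau = -0.3, band = c(2, 6),
                      duration = 300, rate = 54)
  sp2 <- pac_spectrum(s2$epochs, f2_grid = seq(2, 6, by = 0.5))
  val_neg <- mean(phase_slope_index(sp2)$psi[i, , 1], na.rm = TRUE)
  expect_gt(val_pos, 0)
  expect_lt(val_neg, 0)

  # zero lag: |psi| within the epoch-shuffle surrogate null band
  s3 <- coupled_setup(seed = 10, m = 0.6, tau = 0, band = c(2, 6),
                      duration = 300, rate = 54)
  sp3 <- pac_spectrum(s3$epochs, f2_grid = seq(2, 6, by = 0.5))
  val0 <- mean(phase_slope_index(sp3)$psi[i, , 1], na.rm = TRUE)
  null_vals <- vapply(1:12, function(k) {
    su <- surrogate_spectrum(s3$epochs, sp3$f1_grid, seq(2, 6, by = 0.5),
                             seed = k, statistic = "psi")
    mean(su$psi[i, , 1], na.rm = TRUE)
  }, 0)
  expect_lte(abs(val0), max(abs(null_vals)))
})
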