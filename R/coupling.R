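# Cross-frequency coupling between respiratory phase and EEG amplitude.
# PAC is the coherence, over epochs, between the spectral coefficient of the
# (filtered) IP signal at modulation frequency f1 and the coefficient -- also
# at f1 -- of the instantaneous amplitude of the EEG narrowband-filtered at
# carrier frequency f2 (filter bandwidth equal to f1). Epochs are Hann-
# tapered before the transform.

# Fast vectorised linear interpolation of a sampled signal at arbitrary
# times (matrix in, matrix out; NA outside the support).
lin_interp <- function(x, fs, t0, times) {
  pos <- (times - t0) * fs + 1
  fl <- floor(pos)
  w <- pos - fl
  ok <- fl >= 1 & fl < length(x)
  out <- times
  out[] <- NA_real_
  out[ok] <- x[fl[ok]] * (1 - w[ok]) + x[fl[ok] + 1L] * w[ok]
  out
}

#' Paired IP/EEG analysis epochs
#'
#' Segments synchronised IP and EEG signals into windows of `L` seconds with
#' fractional `overlap` on a common time base. The spectral resolution of all
#' downstream estimates is `1/L` (0.25 Hz for the default 4-s epochs). Epochs
#' containing missing samples in either stream are excluded immediately.
#'
#' @param ip single-channel (filtered) IP [time_series()].
#' @param eeg multichannel EEG [time_series()] on the same clock.
#' @param L epoch length in seconds; `L * fs` must be an integer for both
#'   streams.
#' @param overlap fractional overlap between consecutive epochs.
#' @return an object of class `epoch_set`: `starts` (epoch start times, s),
#'   `eeg_order` (EEG epoch pairing permutation; identity until
#'   [permute_pairing()]), `ip` (epochs x samples matrix), `eeg` (the full
#'   EEG, for continuous envelope extraction), `L`, `overlap`, `delta_f`,
#'   `n`, `rejection_log`.
#' @export
make_epochs <- function(ip, eeg, L = 4, overlap = 0.5) {
  stopifnot(inherits(ip, "respac_ts"), inherits(eeg, "respac_ts"))
  m_ip <- L * ip$fs
  m_eeg <- L * eeg$fs
  if (abs(m_ip - round(m_ip)) > 1e-9 || abs(m_eeg - round(m_eeg)) > 1e-9) {
    stop("L * fs must be an integer for both streams")
  }
  m_ip <- round(m_ip); m_eeg <- round(m_eeg)
  t_lo <- max(ip$t0, eeg$t0)
  t_hi <- min(ip$t0 + duration_s(ip), eeg$t0 + duration_s(eeg))
  step <- L * (1 - overlap)
  if (t_hi - t_lo < L) {
    starts <- numeric(0)
  } else {
    starts <- seq(t_lo, t_hi - L + 1e-9, by = step)
  }
  n <- length(starts)
  ip_x <- ts_channel(ip, 1)
  ip_mat <- matrix(NA_real_, n, m_ip)
  idx0 <- round((starts - ip$t0) * ip$fs)
  for (i in seq_len(n)) ip_mat[i, ] <- ip_x[idx0[i] + seq_len(m_ip)]

  log <- data.frame(start = numeric(0), rule = character(0))
  has_na <- apply(ip_mat, 1, anyNA)
  eeg_idx0 <- round((starts - eeg$t0) * eeg$fs)
  for (i in seq_len(n)) {
    if (!has_na[i] &&
        anyNA(eeg$samples[eeg_idx0[i] + seq_len(m_eeg), ])) {
      has_na[i] <- TRUE
    }
  }
  if (any(has_na)) {
    log <- data.frame(start = starts[has_na], rule = "missing-samples")
    starts <- starts[!has_na]
    ip_mat <- ip_mat[!has_na, , drop = FALSE]
  }
  structure(
    list(starts = starts, eeg_order = seq_along(starts), ip = ip_mat,
         eeg = eeg, fs_ip = ip$fs, L = L, overlap = overlap, delta_f = 1 / L,
         n = length(starts), rejection_log = log),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs of %g s (overlap %g, delta_f %g Hz), %d rejected\n",
    x$n, x$L, x$overlap, x$delta_f, nrow(x$rejection_log)
  ))
  invisible(x)
}

epoch_subset <- function(epochs, keep, rule) {
  if (all(keep)) return(epochs)
  epochs$rejection_log <- rbind(
    epochs$rejection_log,
    data.frame(start = epochs$starts[!keep], rule = rule)
  )
  epochs$starts <- epochs$starts[keep]
  epochs$ip <- epochs$ip[keep, , drop = FALSE]
  epochs$eeg_order <- seq_along(epochs$starts)
  epochs$n <- length(epochs$starts)
  epochs
}

# EEG epochs of a single channel (or of a derived signal such as an
# envelope), honouring the pairing permutation.
eeg_epoch_matrix <- function(epochs, x, fs, t0) {
  m <- round(epochs$L * fs)
  starts <- epochs$starts[epochs$eeg_order]
  idx0 <- round((starts - t0) * fs)
  out <- matrix(NA_real_, length(starts), m)
  for (i in seq_along(starts)) out[i, ] <- x[idx0[i] + seq_len(m)]
  out
}

#' Reject artifact and irregular-respiration epochs
#'
#' Applies, in order: (1) epochs with fewer than `min_breaths` detected
#' breaths, or overlapping an interval discarded as noise/shallow breathing,
#' are removed; (2) epochs whose standard deviation exceeds 3 times the mean
#' or the median of all epochs' SDs are removed, evaluated separately for IP
#' and for each EEG channel; (3) epochs containing an absolute value greater
#' than 10 times the mean or the median of the epoch SDs are removed. The
#' rejection log records the first rule triggered per epoch.
#'
#' @param epochs an [make_epochs()] result.
#' @param record a [breath_record()] on the same clock (classified when long
#'   IBIs exist), or `NULL` to skip rule 1.
#' @param min_breaths minimum detected breaths per epoch.
#' @param centre `"either"` rejects when the mean- or the median-based bound
#'   is exceeded; `"mean"`/`"median"` use a single bound.
#' @return the pruned `epoch_set`; `n = 0` (flagged downstream) when all
#'   epochs are rejected.
#' @export
reject_epochs <- function(epochs, record = NULL, min_breaths = 3,
                          centre = c("either", "mean", "median")) {
  centre <- match.arg(centre)
  exceeded <- function(stat, mult) {
    ok_mean <- stat > mult * mean(stat)
    ok_med <- stat > mult * stats::median(stat)
    switch(centre, either = ok_mean | ok_med, mean = ok_mean, median = ok_med)
  }
  if (!is.null(record)) {
    nb <- vapply(epochs$starts, function(s) {
      sum(record$onsets >= s & record$onsets < s + epochs$L)
    }, 0L)
    keep <- nb >= min_breaths
    epochs <- epoch_subset(epochs, keep, "fewer-than-min-breaths")
    bad <- record$long_ibis[record$long_ibis$label %in% "noise-or-shallow", ]
    if (nrow(bad) && epochs$n) {
      overlap <- vapply(epochs$starts, function(s) {
        any(bad$start < s + epochs$L & bad$end > s)
      }, TRUE)
      epochs <- epoch_subset(epochs, !overlap, "discarded-interval")
    }
  }
  if (epochs$n == 0) return(epochs)

  eeg_mats <- lapply(epochs$eeg$labels, function(ch) {
    eeg_epoch_matrix(epochs, ts_channel(epochs$eeg, ch), epochs$eeg$fs,
                     epochs$eeg$t0)
  })
  sd_sets <- c(list(apply(epochs$ip, 1, stats::sd)),
               lapply(eeg_mats, function(m) apply(m, 1, stats::sd)))
  bad_sd <- Reduce(`|`, lapply(sd_sets, exceeded, mult = 3))
  epochs <- epoch_subset(epochs, !bad_sd, "sd-bound")
  if (epochs$n == 0) return(epochs)

  keep_idx <- which(!bad_sd)
  max_sets <- c(list(apply(abs(epochs$ip), 1, max)),
                lapply(eeg_mats, function(m) {
                  apply(abs(m[keep_idx, , drop = FALSE]), 1, max)
                }))
  sd_sets <- lapply(sd_sets, function(s) s[keep_idx])
  bad_amp <- rep(FALSE, epochs$n)
  for (k in seq_along(max_sets)) {
    s <- sd_sets[[k]]
    bound <- switch(centre,
      either = pmin(10 * mean(s), 10 * stats::median(s)),
      mean = 10 * mean(s),
      median = 10 * stats::median(s)
    )
    bad_amp <- bad_amp | max_sets[[k]] > bound
  }
  epoch_subset(epochs, !bad_amp, "amplitude-bound")
}

#' Coherency of paired complex spectral coefficients
#'
#' The estimator kernel: given per-epoch coefficients `x` (IP at f1) and `y`
#' (EEG envelope at f1), returns the complex coherency
#' `sum(x * Conj(y)) / sqrt(sum |x|^2 * sum |y|^2)`, whose magnitude is the
#' coherence. For independent coefficients the expected magnitude is
#' approximately `sqrt(pi / 4) / sqrt(N)` (small-sample bias).
#'
#' @param x,y complex vectors of equal length N >= 2.
#' @return a single complex coherency value.
#' @export
coherency <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must pair epoch-wise")
  if (length(x) < 2) stop("coherence of a single epoch is degenerate (N < 2)")
  sum(x * Conj(y)) / sqrt(sum(Mod(x)^2) * sum(Mod(y)^2))
}

#' Cross-frequency coherency at one (f1, f2) cell
#'
#' @param epochs an [epoch_set].
#' @param f1 modulation (respiratory) frequency in Hz; must lie on the `1/L`
#'   grid.
#' @param f2 EEG carrier frequency in Hz; the envelope filter bandwidth
#'   equals `f1`.
#' @param channel EEG channel label or index.
#' @return complex coherency; its `Mod()` is the PAC coherence.
#' @export
pac_coherence <- function(epochs, f1, f2, channel = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$n < 2) stop("need at least 2 retained epochs")
  if (f1 <= 0 || abs(f1 / epochs$delta_f - round(f1 / epochs$delta_f)) > 1e-9) {
    stop(sprintf("f1 = %g Hz is not on the %g Hz grid", f1, epochs$delta_f))
  }
  env <- envelope(epochs$eeg, f2, bandwidth = f1)
  y_mat <- eeg_epoch_matrix(epochs, ts_channel(env, channel), env$fs, env$t0)
  x <- dft_coef_epochs(epochs$ip, epochs$fs_ip, f1)
  y <- dft_coef_epochs(y_mat, env$fs, f1)
  coherency(x, y)
}

#' Full cross-frequency coherence spectrum
#'
#' Computes the complex coherency on an (f1, f2) grid for each EEG channel.
#' Cells whose envelope band falls outside (0, Nyquist) are set to `NA`.
#'
#' @param epochs an [epoch_set].
#' @param f1_grid modulation frequencies (Hz) on the `1/L` grid; default
#'   0.25-2 Hz in 0.25 Hz steps.
#' @param f2_grid carrier frequencies (Hz); default 0.5-25 Hz in 0.25 Hz
#'   steps.
#' @param channels channel labels to analyse (default: all).
#' @return an object of class `coupling_result`: `f1_grid`, `f2_grid`,
#'   `channels`, `coherency` (complex array f1 x f2 x channel), `coherence`
#'   (its magnitude), `delta_f`, `n_epochs`.
#' @export
pac_spectrum <- function(epochs, f1_grid = seq(0.25, 2, by = 0.25),
                         f2_grid = seq(0.5, 25, by = 0.25),
                         channels = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$n < 2) stop("need at least 2 retained epochs")
  if (is.null(channels)) channels <- epochs$eeg$labels
  eeg <- epochs$eeg
  sub <- time_series(eeg$samples[, channels, drop = FALSE], fs = eeg$fs,
                     t0 = eeg$t0, labels = channels)
  nyq <- eeg$fs / 2
  coh <- array(NA_complex_,
               dim = c(length(f1_grid), length(f2_grid), length(channels)),
               dimnames = list(NULL, NULL, channels))
  m_eeg <- round(epochs$L * eeg$fs)
  tt <- (seq_len(m_eeg) - 1L) / eeg$fs
  w <- hann_window(m_eeg)
  starts <- epochs$starts[epochs$eeg_order]
  idx0 <- round((starts - eeg$t0) * eeg$fs)
  slice_idx <- outer(idx0, seq_len(m_eeg), `+`)
  for (a in seq_along(f1_grid)) {
    f1 <- f1_grid[a]
    x <- dft_coef_epochs(epochs$ip, epochs$fs_ip, f1)
    kern <- w * exp(-2i * pi * f1 * tt)
    for (b in seq_along(f2_grid)) {
      f2 <- f2_grid[b]
      if (f2 - f1 / 2 <= 0 || f2 + f1 / 2 >= nyq) next
      env <- Mod(fft_bandpass(sub$samples, sub$fs, max(f2 - f1 / 2, 0.25),
                              f2 + f1 / 2, analytic = TRUE))
      for (ch in seq_along(channels)) {
        e <- env[, ch]
        mat <- matrix(e[slice_idx], nrow = length(starts))
        aw <- as.numeric(mat %*% w) / sum(w)  # taper-weighted mean removal
        y <- as.complex(mat %*% kern) - aw * sum(kern)
        coh[a, b, ch] <- coherency(x, y)
      }
    }
  }
  structure(
    list(f1_grid = f1_grid, f2_grid = f2_grid, channels = channels,
         coherency = coh, coherence = Mod(coh), delta_f = epochs$delta_f,
         n_epochs = epochs$n),
    class = "coupling_result"
  )
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf(
    "<coupling_result> %d x %d (f1 x f2) grid, %d channel(s), N = %d epochs, delta_f = %g Hz\n",
    length(x$f1_grid), length(x$f2_grid), length(x$channels), x$n_epochs,
    x$delta_f
  ))
  invisible(x)
}

#' Band-averaged coupling
#'
#' Mean coherence over the grid cells whose carrier frequency f2 lies inside
#' each band, optionally restricted to a significance mask.
#'
#' @param result a [pac_spectrum()] result.
#' @param bands a [frequency_bands()] object or a named list of `c(lo, hi)`.
#' @param mask optional logical array matching `result$coherence` (e.g. from
#'   [fdr_mask()]); only masked-in cells are averaged.
#' @param channels channels to include (default: all in the result).
#' @return a bands x channels matrix of mean coherences; `NA` (flagged
#'   missing) where the mask leaves no cell in a band.
#' @export
band_average <- function(result, bands, mask = NULL, channels = NULL) {
  stopifnot(inherits(result, "coupling_result"))
  if (is.null(channels)) channels <- result$channels
  if (!is.null(mask) && !identical(dim(mask), dim(result$coherence))) {
    stop("mask shape must match the coherence grid")
  }
  out <- matrix(NA_real_, length(bands), length(channels),
                dimnames = list(names(bands), channels))
  for (bi in seq_along(bands)) {
    b <- bands[[bi]]
    cols <- result$f2_grid >= b[1] & result$f2_grid <= b[2]
    for (ch in seq_along(channels)) {
      chi <- match(channels[ch], result$channels)
      vals <- result$coherence[, cols, chi]
      if (!is.null(mask)) vals <- vals[mask[, cols, chi]]
      vals <- vals[!is.na(vals)]
      if (length(vals)) out[bi, ch] <- mean(vals)
    }
  }
  out
}

#' PAC resolved across the respiratory cycle
#'
#' Estimates coupling at `n_points` (default 50) equally spaced phase points
#' within the breath cycle. At each phase point, a short window (default 2/3
#' s) centred at that phase is gathered from every analysable breath; the
#' coherence between the Hann-tapered spectral coefficients of the IP window
#' and of the band-limited EEG envelope window, across breaths, is the
#' time-resolved PAC. Both windows are resampled onto a common grid so the
#' coefficients share one modulation frequency (the first non-zero bin,
#' `1/window` Hz).
#'
#' @param ip filtered IP [time_series()].
#' @param eeg EEG [time_series()] on the same clock.
#' @param record a classified [breath_record()].
#' @param bands named list of EEG bands (default delta and theta).
#' @param window window length in seconds (default 2/3 s, sub-cycle so that
#'   temporal changes appear within the respiratory cycle).
#' @param channels EEG channels to pool (coefficients are concatenated across
#'   channels before the coherence, default FCz and Cz).
#' @param n_points phase points per cycle.
#' @return an object of class `cycle_pac`: `phase_grid` (radians),
#'   `coherence` (bands x n_points), `window`, `n_breaths`.
#' @export
cycle_pac <- function(ip, eeg, record,
                      bands = list(delta = c(0.5, 4), theta = c(4, 8)),
                      window = 2 / 3, channels = c("FCz", "Cz"),
                      n_points = 50) {
  pf <- phase_function(record)
  cyc <- pf$cycles
  ok_len <- cyc$dur >= window
  if (mean(!ok_len) > 0.5) {
    warning("cycle shorter than the window in > 50% of breaths; skipped")
  }
  cyc <- cyc[ok_len, , drop = FALSE]
  # windows must lie inside both signals
  t_lo <- max(ip$t0, eeg$t0) + window
  t_hi <- min(ip$t0 + duration_s(ip), eeg$t0 + duration_s(eeg)) - window
  cyc <- cyc[cyc$onset > t_lo & cyc$onset + cyc$dur < t_hi, , drop = FALSE]
  if (nrow(cyc) < 30) stop("need at least 30 analysable breaths")

  m <- 48L  # common resampling grid within the window
  rel <- seq(-window / 2, window / 2, length.out = m)
  f1w <- 1 / window
  w <- hann_window(m)
  kern <- w * exp(-2i * pi * f1w * (rel - rel[1]))
  channels <- intersect(channels, eeg$labels)
  if (!length(channels)) stop("no requested channel present in the EEG")

  ip_x <- ts_channel(ip, 1)
  envs <- lapply(bands, function(b) {
    e <- envelope(
      time_series(eeg$samples[, channels, drop = FALSE], fs = eeg$fs,
                  t0 = eeg$t0, labels = channels),
      f2 = mean(b), bandwidth = diff(b)
    )
    e
  })

  phase_grid <- 2 * pi * (seq_len(n_points) - 1) / n_points
  coh <- matrix(NA_real_, length(bands), n_points,
                dimnames = list(names(bands), NULL))
  tap_coef <- function(mat) {
    aw <- as.numeric(mat %*% w) / sum(w)  # taper-weighted mean removal
    as.complex(mat %*% kern) - aw * sum(kern)
  }
  for (p in seq_len(n_points)) {
    centres <- cyc$onset + (p - 1) / n_points * cyc$dur
    tmat <- outer(centres, rel, `+`)
    x <- tap_coef(lin_interp(ip_x, ip$fs, ip$t0, tmat))
    for (bi in seq_along(bands)) {
      env <- envs[[bi]]
      xs <- ys <- NULL
      for (ch in channels) {
        ew <- lin_interp(ts_channel(env, ch), env$fs, env$t0, tmat)
        ys <- c(ys, tap_coef(ew))
        xs <- c(xs, x)
      }
      coh[bi, p] <- Mod(coherency(xs, ys))
    }
  }
  structure(
    list(phase_grid = phase_grid, coherence = coh, window = window,
         n_breaths = nrow(cyc), channels = channels),
    class = "cycle_pac"
  )
}

#' Breath-locked time-frequency amplitude map
#'
#' For each carrier frequency, the narrowband EEG envelope is resampled onto
#' the 50-point respiratory-cycle grid and averaged over breaths (and the
#' requested channels). Per-band traces are means over the carrier
#' frequencies inside each band.
#'
#' @param eeg EEG [time_series()].
#' @param record a classified [breath_record()].
#' @param f_grid carrier frequencies in Hz (default 0.5-25 in 0.5 Hz steps,
#'   covering the delta-beta range).
#' @param channels channels averaged into the map.
#' @param bands a [frequency_bands()] for the band traces.
#' @param n_points phase points per cycle.
#' @param ip optional filtered IP signal; when given, its breath-locked
#'   average is returned as `ip_trace`.
#' @return an object of class `breath_tf`: `f_grid`, `phase_grid`, `map`
#'   (frequency x phase mean amplitude), `band_traces` (bands x phase),
#'   `n_breaths`, optional `ip_trace`.
#' @export
breath_locked_tf <- function(eeg, record, f_grid = seq(0.5, 25, by = 0.5),
                             channels = c("FCz", "Cz"),
                             bands = frequency_bands(), n_points = 50,
                             ip = NULL) {
  pf <- phase_function(record)
  cyc <- pf$cycles
  t_lo <- eeg$t0
  t_hi <- eeg$t0 + duration_s(eeg)
  cyc <- cyc[cyc$onset > t_lo & cyc$onset + cyc$dur < t_hi, , drop = FALSE]
  if (nrow(cyc) < 30) stop("need at least 30 analysable breaths")
  channels <- intersect(channels, eeg$labels)
  grid <- (seq_len(n_points) - 1) / n_points
  tmat <- outer(cyc$onset, rep(1, n_points)) +
    outer(cyc$dur, grid)
  bw <- resp_frequency(record, grid_hz = 0.25)
  sub <- time_series(eeg$samples[, channels, drop = FALSE], fs = eeg$fs,
                     t0 = eeg$t0, labels = channels)
  mp <- matrix(NA_real_, length(f_grid), n_points)
  for (fi in seq_along(f_grid)) {
    f2 <- f_grid[fi]
    if (f2 - bw / 2 <= 0 || f2 + bw / 2 >= eeg$fs / 2) next
    env <- envelope(sub, f2, bandwidth = bw)
    acc <- 0
    for (ch in channels) {
      acc <- acc + lin_interp(ts_channel(env, ch), env$fs, env$t0, tmat)
    }
    mp[fi, ] <- colMeans(acc / length(channels), na.rm = TRUE)
  }
  traces <- matrix(NA_real_, length(bands), n_points,
                   dimnames = list(names(bands), NULL))
  for (bi in seq_along(bands)) {
    rows <- f_grid >= bands[[bi]][1] & f_grid <= bands[[bi]][2]
    traces[bi, ] <- colMeans(mp[rows, , drop = FALSE], na.rm = TRUE)
  }
  ip_trace <- NULL
  if (!is.null(ip)) {
    ip_trace <- colMeans(lin_interp(ts_channel(ip, 1), ip$fs, ip$t0, tmat),
                         na.rm = TRUE)
  }
  structure(
    list(f_grid = f_grid, phase_grid = 2 * pi * grid, map = mp,
         band_traces = traces, n_breaths = nrow(cyc), ip_trace = ip_trace),
    class = "breath_tf"
  )
}

#' Cross-frequency phase-slope index
#'
#' Directionality of the coupling: a consistent time lag between the EEG
#' envelope and respiration makes the coherency phase change linearly with
#' the modulation frequency, and the phase-slope index accumulates the
#' imaginary parts of conjugate products of coherencies at neighbouring
#' modulation frequencies over a window of width `beta` (default 1 Hz, four
#' times the 0.25 Hz resolution of 4-s epochs). The sign is calibrated on
#' synthetic known-lag data so that positive values mean the EEG amplitude
#' leads respiration.
#'
#' @param result a [pac_spectrum()] result (complex coherencies).
#' @param beta slope-estimation bandwidth in Hz; must be at least 4 times the
#'   grid resolution.
#' @return an object of class `psi_map`: `psi` (real array f1 x f2 x channel,
#'   `NA` where the window exceeds the grid edge), `beta`, `delta_f`,
#'   `channels`, `convention`.
#' @export
phase_slope_index <- function(result, beta = 1.0) {
  stopifnot(inherits(result, "coupling_result"))
  df <- result$delta_f
  if (beta < 4 * df - 1e-9) {
    stop("`beta` must be at least 4 times the frequency resolution")
  }
  f1 <- result$f1_grid
  psi <- array(NA_real_, dim = dim(result$coherency),
               dimnames = dimnames(result$coherency))
  for (a in seq_along(f1)) {
    lo <- f1[a] - beta / 2
    hi <- f1[a] + beta / 2
    if (lo < min(f1) - 1e-9 || hi > max(f1) + 1e-9) next
    take <- which(f1 >= lo - 1e-9 & f1 <= hi + 1e-9)
    pairs <- take[take < length(f1)]
    pairs <- pairs[f1[pairs + 1L] <= hi + 1e-9]
    if (length(pairs) < 2) next
    prod <- Conj(result$coherency[pairs, , , drop = FALSE]) *
      result$coherency[pairs + 1L, , , drop = FALSE]
    # -1: positive psi = EEG amplitude leads respiration
    psi[a, , ] <- -apply(Im(prod), c(2, 3), sum)
  }
  structure(
    list(psi = psi, beta = beta, delta_f = df, channels = result$channels,
         convention = "positive = EEG amplitude leads respiration"),
    class = "psi_map"
  )
}
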