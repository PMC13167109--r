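# Breath and apnoea identification from impedance pneumography: band-pass
# filtering, adaptive amplitude-threshold breath detection, classification of
# long inter-breath intervals into apnoea vs noise/shallow breathing, apnoea
# rate, and the respiratory phase function.

LONG_IBI_S <- 15

#' Breath record
#'
#' Container for detected breath onsets and derived inter-breath intervals.
#' Intervals of 15 s or longer are candidate apnoeas and receive a label
#' (`"apnoea"` or `"noise-or-shallow"`) from [classify_long_ibis()].
#'
#' @param onsets breath onset times in seconds (strictly increasing).
#' @param fs sampling rate of the source signal, Hz.
#' @param span `c(start, end)` of the analysed signal in seconds.
#' @param na_seconds total duration of missing-sample gaps, excluded from the
#'   analysed time.
#' @param flagged logical; `TRUE` when no breath was detected.
#' @return an object of class `breath_record` with elements `onsets`, `ibis`,
#'   `long_ibis` (data.frame `index`, `start`, `end`, `ibi`, `label`), `fs`,
#'   `span`, `na_seconds`, `analysed_hours`, `flagged`.
#' @export
breath_record <- function(onsets, fs, span = range(onsets), na_seconds = 0,
                          flagged = FALSE) {
  onsets <- as.numeric(onsets)
  if (length(onsets) && is.unsorted(onsets, strictly = TRUE)) {
    stop("breath onsets must be strictly increasing")
  }
  ibis <- diff(onsets)
  li <- which(ibis >= LONG_IBI_S)
  long_ibis <- data.frame(
    index = li, start = onsets[li], end = onsets[li + 1], ibi = ibis[li],
    label = rep(NA_character_, length(li)), stringsAsFactors = FALSE
  )
  structure(
    list(onsets = onsets, ibis = ibis, long_ibis = long_ibis, fs = fs,
         span = span, na_seconds = na_seconds,
         analysed_hours = (diff(span) - na_seconds) / 3600,
         flagged = flagged),
    class = "breath_record"
  )
}

#' @export
print.breath_record <- function(x, ...) {
  cat(sprintf(
    "<breath_record> %d breaths over %.1f min; %d long IBI(s) (%d apnoea)%s\n",
    length(x$onsets), diff(x$span) / 60, nrow(x$long_ibis),
    sum(x$long_ibis$label == "apnoea", na.rm = TRUE),
    if (x$flagged) " [FLAGGED: no breaths]" else ""
  ))
  invisible(x)
}

#' Band-pass filter an impedance pneumography signal
#'
#' Zero-phase band-pass (default 0.1-2 Hz) attenuating movement drift and the
#' cardiac artifact (neonatal heart rates are ~2-3 Hz) while preserving the
#' respiratory frequencies. Transition bands are 0.05 Hz below the lower edge
#' and 0.2 Hz above the upper edge, so a 2.2 Hz cardiac component falls at
#' the stop-band edge.
#'
#' @param ip single-channel [time_series()].
#' @param band pass-band `c(low, high)` in Hz.
#' @return the filtered `respac_ts`.
#' @export
filter_ip <- function(ip, band = c(0.1, 2)) {
  stopifnot(inherits(ip, "respac_ts"))
  if (ip$fs < 25) stop("IP sampling rate must be >= 25 Hz")
  flen <- 1 / band[1]  # nominal impulse-response length, seconds
  if (duration_s(ip) < 10 * flen) {
    stop(sprintf("signal too short: need >= %g s (10 filter lengths)",
                 10 * flen))
  }
  y <- fft_bandpass(ip$samples, ip$fs, band[1], band[2], trans = c(0.05, 0.2))
  y[is.na(ip$samples)] <- NA
  time_series(y, fs = ip$fs, t0 = ip$t0, labels = ip$labels)
}

#' Detect breaths with an adaptive amplitude threshold
#'
#' A breath onset is marked where the filtered IP signal crosses, rising from
#' below, a threshold of `factor` (default 0.4) times the signal's standard
#' deviation over the window spanning the preceding `window_breaths` (default
#' 15) detected breaths. Before 15 breaths have been detected the global
#' record SD is used. The SD-relative threshold makes detection invariant to
#' overall signal scaling.
#'
#' Each detected crossing is then refined backwards to the preceding signal
#' trough, which marks the start of inspiration, so that phase 0 of the
#' respiratory cycle is anchored at inspiration onset rather than part-way up
#' the inspiratory rise (`refine = "crossing"` keeps the raw crossing times).
#'
#' @param ip_filtered filtered single-channel [time_series()] (see
#'   [filter_ip()]).
#' @param factor threshold as a multiple of the running SD.
#' @param window_breaths number of preceding breaths defining the SD window.
#' @param refractory_s minimum spacing between onsets in seconds.
#' @param refine onset timing: `"trough"` (default) or `"crossing"`.
#' @return a [breath_record()]; `flagged = TRUE` with zero onsets when the
#'   signal never crosses the threshold.
#' @export
detect_breaths <- function(ip_filtered, factor = 0.4, window_breaths = 15,
                           refractory_s = 0.2,
                           refine = c("trough", "crossing")) {
  refine <- match.arg(refine)
  stopifnot(inherits(ip_filtered, "respac_ts"))
  if (duration_s(ip_filtered) < 30) stop("record must be at least 30 s")
  x <- ts_channel(ip_filtered, 1)
  fs <- ip_filtered$fs
  n <- length(x)
  na_seconds <- sum(is.na(x)) / fs
  global_sd <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(global_sd) || global_sd == 0) global_sd <- 1

  onset_idx <- integer(0)
  thr <- factor * global_sd
  i <- 1L
  chunk <- max(64L, as.integer(60 * fs))
  refr <- as.integer(round(refractory_s * fs))
  while (i < n) {
    j_hi <- min(i + chunk, n - 1L)
    seg <- i:j_hi
    below <- x[seg] < thr
    above <- x[seg + 1L] >= thr
    hit <- which(below & above)
    if (!length(hit)) {
      i <- j_hi + 1L
      next
    }
    k <- seg[hit[1]] + 1L
    onset <- k
    if (refine == "trough") {
      lb <- if (length(onset_idx)) onset_idx[length(onset_idx)] + 1L else 1L
      while (onset > lb && !is.na(x[onset - 1L]) && x[onset - 1L] <= x[onset]) {
        onset <- onset - 1L
      }
    }
    onset_idx <- c(onset_idx, onset)
    nb <- length(onset_idx)
    w0 <- onset_idx[max(1L, nb - window_breaths)]
    wsd <- stats::sd(x[w0:k], na.rm = TRUE)
    if (is.finite(wsd) && wsd > 0) thr <- factor * wsd
    i <- k + refr
  }
  if (!length(onset_idx)) {
    return(breath_record(numeric(0), fs,
                         span = c(ip_filtered$t0,
                                  ip_filtered$t0 + duration_s(ip_filtered)),
                         na_seconds = na_seconds, flagged = TRUE))
  }
  breath_record(
    ip_filtered$t0 + (onset_idx - 1L) / fs, fs,
    span = c(ip_filtered$t0, ip_filtered$t0 + duration_s(ip_filtered)),
    na_seconds = na_seconds
  )
}

#' Features of a long inter-breath interval
#'
#' Two features drive the default classifier: the within-interval signal SD
#' relative to the SD of surrounding normal breathing, and the fraction of
#' spectral power inside the respiratory band (0.3-2 Hz). A genuine apnoea is
#' near-flat and aperiodic (both features low); shallow breathing keeps its
#' respiratory periodicity.
#'
#' @param record a [breath_record()].
#' @param ip the raw (unfiltered) IP [time_series()].
#' @param margin_s seconds trimmed from each end of the interval before
#'   computing features.
#' @return data.frame with one row per long IBI: `index`, `rel_sd`,
#'   `resp_power_frac`.
#' @export
long_ibi_features <- function(record, ip, margin_s = 2) {
  x <- ts_channel(ip, 1)
  tt <- ts_times(ip)
  # SD of normal breathing: samples inside short (< 15 s) IBIs, i.e. the
  # detected span minus the (few) long intervals
  normal <- rep(FALSE, length(x))
  if (length(record$onsets) > 1) {
    normal[tt >= record$onsets[1] &
             tt < record$onsets[length(record$onsets)]] <- TRUE
    for (r in seq_len(nrow(record$long_ibis))) {
      normal[tt >= record$long_ibis$start[r] &
               tt < record$long_ibis$end[r]] <- FALSE
    }
  }
  sd_breathing <- stats::sd(x[normal], na.rm = TRUE)
  if (!is.finite(sd_breathing) || sd_breathing == 0) {
    sd_breathing <- stats::sd(x, na.rm = TRUE)
  }
  out <- record$long_ibis[, "index", drop = FALSE]
  out$rel_sd <- out$resp_power_frac <- NA_real_
  for (r in seq_len(nrow(out))) {
    a <- record$long_ibis$start[r] + margin_s
    b <- record$long_ibis$end[r] - margin_s
    seg <- x[tt >= a & tt <= b]
    seg <- seg[!is.na(seg)]
    if (length(seg) < 8) next
    out$rel_sd[r] <- stats::sd(seg) / sd_breathing
    spec <- Mod(stats::fft(seg - mean(seg)))^2
    freqs <- (seq_along(spec) - 1) * ip$fs / length(spec)
    half <- freqs <= ip$fs / 2
    resp <- half & freqs >= 0.3 & freqs <= 2
    out$resp_power_frac[r] <- sum(spec[resp]) / sum(spec[half])
  }
  out
}

#' Default long-IBI classifier
#'
#' Labels an interval `"apnoea"` when the within-interval SD is below 30% of
#' the surrounding breathing SD *and* less than half of its spectral power
#' lies in the respiratory band; otherwise `"noise-or-shallow"`. Thresholds
#' are exposed as arguments so a trained model of the same interface can
#' replace the rule.
#'
#' @param features data.frame from [long_ibi_features()].
#' @param rel_sd_max,resp_frac_max decision thresholds.
#' @return character vector of labels.
#' @export
default_ibi_classifier <- function(features, rel_sd_max = 0.3,
                                   resp_frac_max = 0.5) {
  ifelse(
    !is.na(features$rel_sd) & features$rel_sd < rel_sd_max &
      !is.na(features$resp_power_frac) &
      features$resp_power_frac < resp_frac_max,
    "apnoea", "noise-or-shallow"
  )
}

#' Classify long inter-breath intervals
#'
#' Every IBI of 15 s or longer is labelled apnoea or noise/shallow breathing.
#' Intervals labelled noise-or-shallow are discarded from further analysis:
#' they count neither towards the apnoea rate nor towards analysis epochs.
#'
#' @param record a [breath_record()] from [detect_breaths()].
#' @param ip the raw IP [time_series()] (features are computed on the
#'   unfiltered signal).
#' @param classifier a function mapping the [long_ibi_features()] data.frame
#'   to a character vector of labels; defaults to
#'   [default_ibi_classifier()].
#' @return the record with `long_ibis$label` filled in.
#' @export
classify_long_ibis <- function(record, ip, classifier = default_ibi_classifier) {
  stopifnot(inherits(record, "breath_record"))
  if (!nrow(record$long_ibis)) return(record)
  feats <- long_ibi_features(record, ip)
  labels <- classifier(feats)
  if (length(labels) != nrow(record$long_ibis) || anyNA(labels)) {
    stop("classifier left long IBIs unlabelled")
  }
  if (!all(labels %in% c("apnoea", "noise-or-shallow"))) {
    stop("labels must be 'apnoea' or 'noise-or-shallow'")
  }
  record$long_ibis$label <- labels
  record
}

#' Apnoea rate in events per hour
#'
#' Counts apnoea-labelled inter-breath intervals and divides by the analysed
#' hours (recording span minus missing-sample gaps, capped at
#' `window_hours`).
#'
#' @param record a labelled [breath_record()].
#' @param window_hours analysis window, at most 24 h.
#' @return events per hour (0 when no apnoea was labelled).
#' @export
apnoea_rate <- function(record, window_hours = 24) {
  stopifnot(inherits(record, "breath_record"))
  if (window_hours <= 0 || window_hours > 24) {
    stop("`window_hours` must lie in (0, 24]")
  }
  if (nrow(record$long_ibis) && anyNA(record$long_ibis$label)) {
    stop("long IBIs must be classified before computing the apnoea rate")
  }
  hours <- min(record$analysed_hours, window_hours)
  if (!is.finite(hours) || hours <= 0) stop("zero analysable hours")
  sum(record$long_ibis$label == "apnoea") / hours
}

#' Respiratory phase function from detected breaths
#'
#' Phase increases linearly from 0 at each breath onset to 2*pi at the next.
#' Cycles that are long IBIs (candidate apnoeas or discarded intervals) are
#' excluded. The object resamples any synchronised signal onto a grid of
#' `n_points` equally spaced phase points per cycle.
#'
#' @param record a [breath_record()].
#' @param insp_frac fraction of the cycle treated as inspiration (phase 0 =
#'   inspiration onset).
#' @return an object of class `phase_function`: `cycles` (data.frame `onset`,
#'   `dur`), `fn` (vectorised time -> phase, `NA` outside retained cycles),
#'   `insp_frac`, and `resample(ts, channel, n_points = 50)` returning a
#'   cycles x n_points matrix of signal values on the phase grid.
#' @export
phase_function <- function(record, insp_frac = 0.4) {
  stopifnot(inherits(record, "breath_record"))
  if (length(record$onsets) < 2) stop("need at least 2 breath onsets")
  keep <- record$ibis < LONG_IBI_S
  cycles <- data.frame(onset = record$onsets[-length(record$onsets)][keep],
                       dur = record$ibis[keep])
  fn <- function(t) {
    i <- findInterval(t, cycles$onset)
    ph <- rep(NA_real_, length(t))
    ok <- i > 0
    rel <- (t[ok] - cycles$onset[i[ok]]) / cycles$dur[i[ok]]
    rel[rel >= 1] <- NA
    ph[ok] <- 2 * pi * rel
    ph
  }
  resample <- function(ts, channel = 1, n_points = 50) {
    grid <- (seq_len(n_points) - 1) / n_points
    out <- matrix(NA_real_, nrow(cycles), n_points)
    tmin <- ts$t0
    tmax <- ts$t0 + duration_s(ts)
    for (b in seq_len(nrow(cycles))) {
      tb <- cycles$onset[b] + grid * cycles$dur[b]
      if (tb[1] < tmin || tb[n_points] > tmax) next
      out[b, ] <- resample_at(ts, channel, tb)
    }
    out
  }
  structure(
    list(cycles = cycles, fn = fn, insp_frac = insp_frac, resample = resample),
    class = "phase_function"
  )
}

#' Mean respiratory frequency of a record
#'
#' @param record a [breath_record()].
#' @param grid_hz optional grid spacing to round to (e.g. 0.25 Hz, the
#'   spectral resolution of 4-s epochs); `NULL` returns the raw frequency.
#' @return mean breath frequency in Hz over normal (< 15 s) intervals.
#' @export
resp_frequency <- function(record, grid_hz = NULL) {
  ib <- record$ibis[record$ibis < LONG_IBI_S]
  if (!length(ib)) stop("no normal inter-breath intervals")
  f <- 1 / mean(ib)
  if (!is.null(grid_hz)) f <- max(round(f / grid_hz) * grid_hz, grid_hz)
  f
}
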