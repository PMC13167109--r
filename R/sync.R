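# Clock synchronisation between the vital-signs and EEG devices: shared
# annotations give a coarse per-event time difference, ECG windows around
# each annotation refine it by cross-correlation, and the final offset is the
# median over annotations, with quality-control exclusion thresholds.

#' Match annotations between two devices
#'
#' @param a annotations on the vitals clock ([annotation_set()]).
#' @param b annotations on the EEG clock.
#' @return named numeric vector of per-annotation time differences
#'   `time_b - time_a` for ids present in both sets, ordered by `a`'s times.
#'   Errors when fewer than 5 ids are shared.
#' @export
match_annotations <- function(a, b) {
  stopifnot(inherits(a, "annotation_set"), inherits(b, "annotation_set"))
  shared <- intersect(a$ids, b$ids)
  if (length(shared) < 5) {
    stop("insufficient shared annotations (", length(shared), " < 5)")
  }
  ta <- a$times[match(shared, a$ids)]
  tb <- b$times[match(shared, b$ids)]
  ord <- order(ta)
  stats::setNames((tb - ta)[ord], shared[ord])
}

# Normalised cross-correlation of two equally sampled windows; returns the
# lag (seconds, b relative to a) maximising it, with parabolic sub-sample
# interpolation. Ties broken toward the smaller |lag|.
xcorr_lag <- function(a, b, fs, max_lag) {
  a <- a - mean(a); b <- b - mean(b)
  n <- length(a)
  nfft <- stats::nextn(2L * n, 2)
  A <- stats::fft(c(a, rep(0, nfft - n)))
  B <- stats::fft(c(b, rep(0, nfft - n)))
  r <- Re(stats::fft(B * Conj(A), inverse = TRUE)) / nfft
  # lag k (samples): correlation of b shifted left by k against a
  lags <- c(0:(nfft / 2), (-nfft / 2 + 1):(-1))
  keep <- abs(lags) <= round(max_lag * fs)
  r <- r[keep]; lags <- lags[keep]
  peak <- which(r == max(r))
  peak <- peak[which.min(abs(lags[peak]))]
  lag <- lags[peak]
  # parabolic interpolation using the circular neighbours
  rm1 <- r[match(lag - 1L, lags)]
  rp1 <- r[match(lag + 1L, lags)]
  frac <- 0
  if (!is.na(rm1) && !is.na(rp1)) {
    den <- rm1 - 2 * r[peak] + rp1
    if (den < 0) frac <- 0.5 * (rm1 - rp1) / den
  }
  (lag + frac) / fs
}

#' Refine annotation time differences with ECG cross-correlation
#'
#' For each matched annotation, 20-s ECG windows (-10 to +10 s around the
#' annotation on each device's own clock) are resampled to the lower of the
#' two sampling rates and aligned by normalised cross-correlation with
#' parabolic peak interpolation. Windows with zero variance are skipped.
#'
#' @param ecg_vitals,ecg_eeg single-channel [time_series()] on their own
#'   clocks.
#' @param times_vitals,times_eeg matched annotation timestamps (equal length,
#'   same order), each on its device's clock.
#' @param max_lag largest residual lag searched, seconds.
#' @return numeric vector of refined per-annotation differences (seconds to
#'   add to the vitals clock); skipped annotations are dropped. Attribute
#'   `"skipped"` lists the indices of skipped windows.
#' @export
refine_with_ecg <- function(ecg_vitals, ecg_eeg, times_vitals, times_eeg,
                            max_lag = 2) {
  stopifnot(length(times_vitals) == length(times_eeg))
  fs <- min(ecg_vitals$fs, ecg_eeg$fs)
  ta_all <- ts_times(ecg_vitals)
  tb_all <- ts_times(ecg_eeg)
  if (any(times_vitals - 10 < ta_all[1] - 1 / fs) ||
      any(times_vitals + 10 > ta_all[length(ta_all)] + 1 / fs) ||
      any(times_eeg - 10 < tb_all[1] - 1 / fs) ||
      any(times_eeg + 10 > tb_all[length(tb_all)] + 1 / fs)) {
    stop("ECG signals must cover every annotation +/- 10 s window")
  }
  rel <- seq(-10, 10, by = 1 / fs)
  out <- numeric(0)
  skipped <- integer(0)
  for (k in seq_along(times_vitals)) {
    wa <- resample_at(ecg_vitals, 1, times_vitals[k] + rel)
    wb <- resample_at(ecg_eeg, 1, times_eeg[k] + rel)
    if (stats::sd(wa) == 0 || stats::sd(wb) == 0) {
      message("annotation ", k, ": flat ECG window, skipped")
      skipped <- c(skipped, k)
      next
    }
    lag <- xcorr_lag(wa, wb, fs, max_lag)
    out <- c(out, (times_eeg[k] - times_vitals[k]) + lag)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Compute the synchronisation offset with quality control
#'
#' The offset is the median of the (refined, when available) per-annotation
#' time differences. A recording is flagged for exclusion when the SD over
#' annotations exceeds 1 s for the annotation alignment or 0.1 s for the ECG
#' alignment.
#'
#' @param annot_diffs per-annotation differences from [match_annotations()].
#' @param ecg_diffs optional refined differences from [refine_with_ecg()].
#' @return an object of class `sync_result`: `offset` (seconds to add to the
#'   vitals clock), `annot_sd`, `ecg_sd`, `n_annotations`, `excluded`,
#'   `reason`.
#' @export
compute_sync <- function(annot_diffs, ecg_diffs = NULL) {
  if (length(annot_diffs) < 5) stop("need at least 5 annotation differences")
  offset <- if (is.null(ecg_diffs)) stats::median(annot_diffs)
            else stats::median(ecg_diffs)
  annot_sd <- stats::sd(annot_diffs)
  ecg_sd <- if (is.null(ecg_diffs)) NA_real_ else stats::sd(ecg_diffs)
  excluded <- FALSE
  reason <- NA_character_
  if (annot_sd > 1.0) {
    excluded <- TRUE
    reason <- "annotation SD > 1 s"
  } else if (!is.na(ecg_sd) && ecg_sd > 0.1) {
    excluded <- TRUE
    reason <- "ECG alignment SD > 0.1 s"
  }
  structure(
    list(offset = offset, annot_sd = annot_sd, ecg_sd = ecg_sd,
         n_annotations = length(annot_diffs), excluded = excluded,
         reason = reason),
    class = "sync_result"
  )
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf(
    "<sync_result> offset = %.4f s over %d annotations (annot SD %.3f s, ECG SD %s s)%s\n",
    x$offset, x$n_annotations, x$annot_sd,
    ifelse(is.na(x$ecg_sd), "NA", sprintf("%.4f", x$ecg_sd)),
    if (x$excluded) paste0(" EXCLUDED: ", x$reason) else ""
  ))
  invisible(x)
}

#' Synchronise a recording bundle
#'
#' Runs annotation matching, ECG refinement and offset computation, and (if
#' the recording passes quality control) returns the bundle with the vitals
#' streams shifted onto the EEG clock.
#'
#' @param recording a bundle as returned by [read_recording()] or
#'   [gen_recording()].
#' @return a list: `sync` (the [compute_sync()] result) and `recording` (the
#'   shifted bundle, or the original when excluded).
#' @export
sync_recording <- function(recording) {
  d <- match_annotations(recording$annotations_vitals,
                         recording$annotations_eeg)
  shared <- names(d)
  tv <- recording$annotations_vitals$times[
    match(shared, recording$annotations_vitals$ids)]
  te <- recording$annotations_eeg$times[
    match(shared, recording$annotations_eeg$ids)]
  refined <- refine_with_ecg(recording$ecg_vitals, recording$ecg_eeg, tv, te)
  res <- compute_sync(d, refined)
  if (!res$excluded) {
    for (nm in c("ip", "ecg_vitals")) {
      recording[[nm]] <- ts_shift(recording[[nm]], res$offset)
    }
    recording$annotations_vitals <- annotation_set(
      recording$annotations_vitals$times + res$offset,
      recording$annotations_vitals$ids
    )
  }
  list(sync = res, recording = recording)
}
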