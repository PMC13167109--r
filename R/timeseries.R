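#' Uniformly sampled multichannel time series
#'
#' The basic signal container used throughout the pipeline. Samples are stored
#' as a numeric matrix with one column per channel; `t0` is the start offset in
#' seconds on the *recording device's own clock* (EEG and vital-signs clocks
#' differ until [compute_sync()] has been applied). Missing samples (sensor
#' dropouts) are represented as `NA` runs and are excluded at epoching, never
#' interpolated.
#'
#' @param samples numeric vector (single channel) or matrix with one column
#'   per channel.
#' @param fs sampling rate in Hz; must be positive.
#' @param t0 start time in seconds on the device clock. Default 0.
#' @param labels character vector of unique channel names. Defaults to the
#'   matrix column names, or `"ch1"`, `"ch2"`, ... when absent.
#' @return An object of class `respac_ts`: a list with elements `samples`
#'   (matrix), `fs`, `t0`, `labels`.
#' @examples
#' ts <- time_series(sin(2 * pi * seq(0, 10, by = 1 / 62.5)), fs = 62.5)
#' n_samples(ts)
#' @export
time_series <- function(samples, fs, t0 = 0, labels = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples)) stop("`samples` must be a vector or matrix")
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  if (is.null(labels)) {
    labels <- colnames(samples)
    if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(samples)))
  }
  if (length(labels) != ncol(samples)) stop("one label per channel required")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  colnames(samples) <- labels
  structure(
    list(samples = samples, fs = fs, t0 = as.numeric(t0), labels = labels),
    class = "respac_ts"
  )
}

#' @rdname time_series
#' @param ts a `respac_ts` object.
#' @export
n_samples <- function(ts) nrow(ts$samples)

#' @rdname time_series
#' @export
duration_s <- function(ts) nrow(ts$samples) / ts$fs

#' Sample times of a time series
#'
#' @param ts a `respac_ts` object.
#' @return numeric vector of sample times in seconds on the device clock.
#' @export
ts_times <- function(ts) ts$t0 + (seq_len(nrow(ts$samples)) - 1L) / ts$fs

#' Extract one channel as a numeric vector
#'
#' @param ts a `respac_ts` object.
#' @param channel channel label or index.
#' @return numeric vector of samples.
#' @export
ts_channel <- function(ts, channel) {
  if (is.character(channel)) {
    if (!channel %in% ts$labels) stop("no channel named '", channel, "'")
  }
  as.numeric(ts$samples[, channel])
}

#' Shift a time series onto another clock
#'
#' Adds `offset` seconds to the start time, e.g. to apply a [compute_sync()]
#' result to the vital-signs stream.
#'
#' @param ts a `respac_ts` object.
#' @param offset seconds to add to `t0`.
#' @return the shifted `respac_ts`.
#' @export
ts_shift <- function(ts, offset) {
  ts$t0 <- ts$t0 + offset
  ts
}

#' @export
print.respac_ts <- function(x, ...) {
  cat(sprintf(
    "<respac_ts> %d channel(s) x %d samples @ %g Hz, t0 = %g s (%.1f s)\n",
    ncol(x$samples), nrow(x$samples), x$fs, x$t0, duration_s(x)
  ))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Per-recording metadata
#'
#' @param infant_id opaque infant identifier (one infant may own several
#'   recordings).
#' @param pma_weeks postmenstrual age at recording in weeks, in `[28, 42]`.
#' @param ventilation_mode one of `"self-ventilating"`, `"low-flow"`,
#'   `"high-flow"`.
#' @param caffeine logical; caffeine received on the day of the recording.
#' @param vitals_hours hours of vital-signs data used for the apnoea rate,
#'   in `(0, 24]`.
#' @return An object of class `recording_meta`.
#' @export
recording_meta <- function(infant_id, pma_weeks, ventilation_mode,
                           caffeine = FALSE, vitals_hours = 24) {
  ventilation_mode <- match.arg(
    ventilation_mode, c("self-ventilating", "low-flow", "high-flow")
  )
  if (!is.finite(pma_weeks) || pma_weeks < 28 || pma_weeks > 42) {
    stop("`pma_weeks` must lie in [28, 42]")
  }
  if (!is.finite(vitals_hours) || vitals_hours <= 0 || vitals_hours > 24) {
    stop("`vitals_hours` must lie in (0, 24]")
  }
  structure(
    list(
      infant_id = as.character(infant_id), pma_weeks = pma_weeks,
      ventilation_mode = ventilation_mode, caffeine = isTRUE(caffeine),
      vitals_hours = vitals_hours
    ),
    class = "recording_meta"
  )
}

#' Annotation (trigger) set on one device's clock
#'
#' Shared annotations are registered simultaneously on both recording devices
#' and anchor clock synchronisation.
#'
#' @param times event timestamps in seconds, strictly increasing.
#' @param ids unique event identifiers matching events across devices.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(times, ids = seq_along(times)) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("annotation times must be strictly increasing")
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("annotation ids must be unique")
  structure(list(times = times, ids = ids), class = "annotation_set")
}

#' EEG frequency bands
#'
#' Default band edges: delta 0.5-4 Hz, theta 4-8 Hz, alpha 8-13 Hz,
#' beta 13-25 Hz.
#'
#' @param delta,theta,alpha,beta numeric length-2 vectors `c(lower, upper)`
#'   in Hz.
#' @return An object of class `frequency_bands`: a named list of band edges.
#' @export
frequency_bands <- function(delta = c(0.5, 4), theta = c(4, 8),
                            alpha = c(8, 13), beta = c(13, 25)) {
  bands <- list(delta = delta, theta = theta, alpha = alpha, beta = beta)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2]) {
      stop("band '", nm, "' must be c(lower, upper) with lower < upper")
    }
  }
  edges <- unlist(bands)
  ord <- unlist(bands[order(vapply(bands, `[`, 0, 1))])
  lows <- ord[seq(1, length(ord), 2)]
  highs <- ord[seq(2, length(ord), 2)]
  if (any(lows[-1] < highs[-length(highs)])) {
    stop("bands may only overlap at shared edges")
  }
  structure(bands, class = "frequency_bands")
}

#' Validate band edges against the sampling rate
#'
#' @param bands a [frequency_bands()] object.
#' @param fs sampling rate in Hz of the signal the bands will be applied to.
#' @return `bands`, unchanged, if every band edge is below the Nyquist
#'   frequency; otherwise an error.
#' @export
validate_bands <- function(bands, fs) {
  stopifnot(inherits(bands, "frequency_bands"))
  top <- max(vapply(bands, `[`, 0, 2))
  if (fs <= 2 * top) {
    stop(sprintf(
      "sampling rate %g Hz cannot resolve band edge %g Hz (Nyquist %g Hz)",
      fs, top, fs / 2
    ))
  }
  bands
}

# Internal: run code under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
  }
  force(code)
}
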