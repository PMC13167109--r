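# End-to-end per-recording analysis: synchronise, detect breaths, epoch,
# reject, and compute true + surrogate coupling spectra. Convenience layer
# used by the command-line interface and the validation scripts; every step
# is also available individually.

#' Analyse one recording end to end
#'
#' Runs the standard pipeline on a recording bundle: clock synchronisation
#' (unless `assume_synced`), IP filtering, adaptive breath detection,
#' long-IBI classification, 4-s/50%-overlap epoching with artifact rejection,
#' and the cross-frequency coherence spectrum plus one epoch-shuffle
#' surrogate.
#'
#' @param recording a bundle from [read_recording()] or [gen_recording()].
#' @param f1_grid,f2_grid spectral grids (Hz), see [pac_spectrum()].
#' @param channels EEG channels to analyse (default: all).
#' @param L,overlap epoching parameters.
#' @param assume_synced skip synchronisation (signals already share a clock).
#' @param surrogate compute the epoch-shuffle surrogate spectrum.
#' @param seed RNG seed for the surrogate permutation.
#' @param classifier long-IBI classifier, see [classify_long_ibis()].
#' @return a list: `sync` (or `NULL`), `record` (classified
#'   [breath_record()]), `epochs`, `spectrum`, `surrogate` (or `NULL`),
#'   `resp_f1` (mean respiratory frequency on the grid).
#' @export
analyse_recording <- function(recording,
                              f1_grid = seq(0.25, 2, by = 0.25),
                              f2_grid = seq(0.5, 25, by = 0.25),
                              channels = NULL, L = 4, overlap = 0.5,
                              assume_synced = FALSE, surrogate = TRUE,
                              seed = 1, classifier = default_ibi_classifier) {
  sync <- NULL
  if (!assume_synced) {
    s <- sync_recording(recording)
    if (s$sync$excluded) {
      stop("recording excluded at synchronisation QC: ", s$sync$reason)
    }
    sync <- s$sync
    recording <- s$recording
  }
  ipf <- filter_ip(recording$ip)
  record <- detect_breaths(ipf)
  if (record$flagged) stop("no breaths detected")
  record <- classify_long_ibis(record, recording$ip, classifier)
  epochs <- reject_epochs(make_epochs(ipf, recording$eeg, L = L,
                                      overlap = overlap), record)
  if (epochs$n < 2) stop("all epochs rejected")
  spec <- pac_spectrum(epochs, f1_grid, f2_grid, channels)
  surr <- NULL
  if (surrogate) {
    surr <- surrogate_spectrum(epochs, f1_grid, f2_grid, channels,
                               seed = seed)
  }
  list(sync = sync, record = record, epochs = epochs, spectrum = spec,
       surrogate = surr,
       resp_f1 = resp_frequency(record, grid_hz = 1 / L))
}

#' Flatten a coupling result to a long data.frame
#'
#' @param result a [pac_spectrum()] result or [phase_slope_index()] map.
#' @return data.frame with columns `channel`, `f1`, `f2` and the statistic
#'   columns (`coherence`, `coherency_real`, `coherency_imag` or `psi`).
#' @export
coupling_to_df <- function(result) {
  if (inherits(result, "coupling_result")) {
    g <- expand.grid(f1 = result$f1_grid, f2 = result$f2_grid,
                     channel = result$channels, stringsAsFactors = FALSE)
    g$coherence <- as.numeric(result$coherence)
    g$coherency_real <- as.numeric(Re(result$coherency))
    g$coherency_imag <- as.numeric(Im(result$coherency))
    g[, c("channel", "f1", "f2", "coherence", "coherency_real",
          "coherency_imag")]
  } else if (inherits(result, "psi_map")) {
    f1 <- seq_len(dim(result$psi)[1])
    g <- expand.grid(f1_index = f1, f2_index = seq_len(dim(result$psi)[2]),
                     channel = result$channels, stringsAsFactors = FALSE)
    g$psi <- as.numeric(result$psi)
    g
  } else {
    stop("unsupported result type")
  }
}
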