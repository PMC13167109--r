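# Surrogate null for coupling estimates: the EEG-envelope epoch order is
# permuted by a derangement while the respiration epoch order (and every
# within-epoch sample) is left untouched, destroying trial-wise cross-signal
# phase alignment while preserving each signal's own spectra. Group-level
# significance comes from sample-wise dependent t-tests against the surrogate
# spectra, FDR-corrected.

#' Derangement permutation of the epoch pairing
#'
#' Pairs every respiration epoch with a *different* recording's-worth EEG
#' epoch: the returned permutation has no fixed point, so no epoch keeps its
#' true partner. Sampling is shuffle-until-valid with a cap of 1000 tries.
#'
#' @param epochs an [make_epochs()] result with at least 3 epochs.
#' @param seed integer RNG seed (recorded in the output).
#' @return the epoch set with a deranged `eeg_order` and attribute `"seed"`.
#' @export
permute_pairing <- function(epochs, seed = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- epochs$n
  if (n < 3) stop("need at least 3 epochs for a non-trivial derangement")
  perm <- with_seed(seed, {
    for (try in seq_len(1000)) {
      p <- sample.int(n)
      if (all(p != seq_len(n))) break
      p <- NULL
    }
    if (is.null(p)) stop("failed to sample a derangement")
    p
  })
  epochs$eeg_order <- epochs$eeg_order[perm]
  attr(epochs, "seed") <- seed
  epochs
}

#' Surrogate coupling spectrum for one recording
#'
#' Computes the PAC spectrum on epoch-shuffled pairings. One surrogate per
#' recording by default; extra permutations are averaged (coherence
#' magnitudes and PSI maps average; the count is recorded).
#'
#' @param epochs an [epoch_set].
#' @param f1_grid,f2_grid,channels as in [pac_spectrum()].
#' @param n_permutations surrogate draws averaged (default 1).
#' @param seed integer RNG seed; permutation k uses `seed + k - 1`.
#' @param statistic `"coherence"` or `"psi"`.
#' @param beta PSI bandwidth, used when `statistic = "psi"`.
#' @return a `coupling_result` (statistic `"coherence"`) or `psi_map`
#'   (statistic `"psi"`) with attributes `"seed"` and `"n_permutations"`.
#' @export
surrogate_spectrum <- function(epochs, f1_grid = seq(0.25, 2, by = 0.25),
                               f2_grid = seq(0.5, 25, by = 0.25),
                               channels = NULL, n_permutations = 1, seed = 1,
                               statistic = c("coherence", "psi"), beta = 1.0) {
  statistic <- match.arg(statistic)
  if (n_permutations < 1) stop("`n_permutations` must be >= 1")
  acc <- NULL
  out <- NULL
  for (k in seq_len(n_permutations)) {
    perm <- permute_pairing(epochs, seed = seed + k - 1L)
    res <- pac_spectrum(perm, f1_grid, f2_grid, channels)
    if (statistic == "psi") res <- phase_slope_index(res, beta = beta)
    val <- if (statistic == "psi") res$psi else res$coherence
    acc <- if (is.null(acc)) val else acc + val
    out <- res
  }
  if (statistic == "psi") out$psi <- acc / n_permutations
  else out$coherence <- acc / n_permutations
  attr(out, "seed") <- seed
  attr(out, "n_permutations") <- n_permutations
  out
}

#' Sample-wise dependent t-tests of true vs surrogate spectra
#'
#' At every grid cell, a paired (dependent) two-sided t-test across
#' recordings compares the true statistic with its surrogate. Cells with zero
#' variance of the differences are degenerate and get p = 1.
#'
#' @param true_spectra,surrogate_spectra lists (one element per recording, >=
#'   3) of numeric arrays on a common grid — e.g. `$coherence` of
#'   [pac_spectrum()] results or `$psi` of [phase_slope_index()] maps.
#' @return a list of arrays `p` (two-sided p-values), `t`, `df`, `mean_diff`,
#'   each with the grid's dimensions.
#' @export
group_test <- function(true_spectra, surrogate_spectra) {
  if (length(true_spectra) != length(surrogate_spectra)) {
    stop("paired lists of equal length required")
  }
  n <- length(true_spectra)
  if (n < 3) stop("need at least 3 recordings")
  dims <- dim(true_spectra[[1]])
  flat <- function(lst) {
    vapply(lst, function(a) {
      if (!identical(dim(a), dims)) stop("spectra must share one grid")
      as.numeric(a)
    }, numeric(prod(dims)))
  }
  d <- flat(true_spectra) - flat(surrogate_spectra)  # cells x recordings
  ok <- rowSums(!is.na(d)) >= 3
  md <- rowMeans(d, na.rm = TRUE)
  sdd <- apply(d, 1, stats::sd, na.rm = TRUE)
  nn <- rowSums(!is.na(d))
  tval <- md / (sdd / sqrt(nn))
  p <- 2 * stats::pt(-abs(tval), df = nn - 1)
  degen <- ok & (is.na(sdd) | sdd == 0)
  p[degen] <- 1
  tval[degen] <- 0
  p[!ok] <- NA
  shape <- function(v) array(v, dim = dims, dimnames = dimnames(true_spectra[[1]]))
  list(p = shape(p), t = shape(tval), df = shape(nn - 1),
       mean_diff = shape(md))
}

#' FDR-corrected significance mask
#'
#' Benjamini-Hochberg correction pooled jointly over all grid cells and
#' channels. Default alpha levels follow the coupling statistics: 0.001 for
#' coherence maps, 0.05 for phase-slope-index maps.
#'
#' @param p_map array of p-values in `[0, 1]` (`NA` cells stay `NA`).
#' @param alpha FDR level.
#' @return an object of class `significance_mask`: `mask` (logical array),
#'   `p_adjusted`, `alpha`, `n_significant`.
#' @export
fdr_mask <- function(p_map, alpha = 0.001) {
  p <- as.numeric(p_map)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  mask <- !is.na(adj) & adj <= alpha
  structure(
    list(
      mask = array(mask, dim = dim(p_map), dimnames = dimnames(p_map)),
      p_adjusted = array(adj, dim = dim(p_map), dimnames = dimnames(p_map)),
      alpha = alpha, n_significant = sum(mask)
    ),
    class = "significance_mask"
  )
}

#' @export
print.significance_mask <- function(x, ...) {
  cat(sprintf("<significance_mask> %d significant cell(s) at FDR alpha = %g\n",
              x$n_significant, x$alpha))
  invisible(x)
}
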