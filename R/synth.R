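# Synthetic-data generators. Every generator is deterministic under `seed`
# and returns its ground truth alongside the signals, so each pipeline stage
# can be validated against known breath timing, coupling parameters, clock
# offsets and cohort-level effect sizes.

#' Respiration generator settings
#'
#' Defaults emulate quasi-periodic neonatal respiration: 40-60 breaths/min
#' (mean 50), breath-to-breath variability, inserted apnoeas of at least 15 s,
#' additive sensor noise and a cardiac artifact near 2.4 Hz.
#'
#' @param rate mean respiratory rate in breaths/min, in `[20, 90]`.
#' @param rate_sd breath-to-breath rate variability (breaths/min).
#' @param apnoea_rate inserted apnoeas per hour.
#' @param apnoea_duration apnoea duration in seconds; must be >= 15.
#' @param noise_sd additive Gaussian noise SD (signal units; breath waveform
#'   has unit peak amplitude).
#' @param cardiac_amp amplitude of the cardiac artifact.
#' @param cardiac_hz cardiac artifact frequency in Hz.
#' @param insp_frac fraction of the breath cycle spent in inspiration; the
#'   asymmetric raised-cosine cycle makes inspiratory and expiratory halves
#'   distinguishable.
#' @return an object of class `resp_spec`.
#' @export
resp_spec <- function(rate = 50, rate_sd = 5, apnoea_rate = 2,
                      apnoea_duration = 20, noise_sd = 0.05,
                      cardiac_amp = 0.1, cardiac_hz = 2.4, insp_frac = 0.4) {
  if (rate < 20 || rate > 90) stop("`rate` must lie in [20, 90] breaths/min")
  if (apnoea_duration < 15) stop("`apnoea_duration` must be >= 15 s")
  if (insp_frac <= 0 || insp_frac >= 1) stop("`insp_frac` must be in (0, 1)")
  structure(
    list(rate = rate, rate_sd = rate_sd, apnoea_rate = apnoea_rate,
         apnoea_duration = apnoea_duration, noise_sd = noise_sd,
         cardiac_amp = cardiac_amp, cardiac_hz = cardiac_hz,
         insp_frac = insp_frac),
    class = "resp_spec"
  )
}

#' Phase-amplitude coupling settings for the EEG generator
#'
#' @param band `c(low, high)` Hz of the modulated EEG carrier, within
#'   `[0.5, 25]`.
#' @param m modulation depth in `[0, 1]`; the carrier's instantaneous
#'   amplitude is proportional to `1 + m * cos(phase(t + tau) - phi0)`.
#' @param phi0 respiratory phase of maximal amplitude, radians.
#' @param tau lag in seconds by which the EEG envelope leads (+) or trails
#'   (-) the respiratory signal.
#' @param channels channel labels carrying the coupling.
#' @param phase_gate optional `c(lo, hi)` phase range (radians): modulation
#'   is confined to this range under a raised-cosine gate that peaks at the
#'   gate centre and vanishes smoothly at its edges (used to emulate
#'   inspiration-only coupling).
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(band = c(4, 8), m = 0.4, phi0 = 0, tau = 0,
                          channels = c("FCz", "Cz"), phase_gate = NULL) {
  if (m < 0 || m > 1) stop("`m` must lie in [0, 1]")
  if (band[1] < 0.5 || band[2] > 25 || band[1] >= band[2]) {
    stop("`band` must lie within [0.5, 25] Hz with low < high")
  }
  structure(
    list(band = band, m = m, phi0 = phi0, tau = tau, channels = channels,
         phase_gate = phase_gate),
    class = "coupling_spec"
  )
}

breath_amplitude <- function(theta, insp_frac) {
  a <- numeric(length(theta))
  ins <- !is.na(theta) & theta >= 0 & theta < insp_frac
  ex <- !is.na(theta) & theta >= insp_frac & theta < 1
  a[ins] <- 0.5 * (1 - cos(pi * theta[ins] / insp_frac))
  a[ex] <- 0.5 * (1 + cos(pi * (theta[ex] - insp_frac) / (1 - insp_frac)))
  a
}

make_phase_fn <- function(onsets, durs) {
  force(onsets); force(durs)
  function(t) {
    i <- findInterval(t, onsets)
    ph <- rep(NA_real_, length(t))
    ok <- i > 0
    rel <- (t[ok] - onsets[i[ok]]) / durs[i[ok]]
    rel[rel >= 1] <- NA
    ph[ok] <- 2 * pi * rel
    ph
  }
}

#' Generate a synthetic impedance-pneumography signal
#'
#' Breath cycles are asymmetric raised cosines (shorter inspiration than
#' expiration) with onset = start of inspiration; apnoeas are near-flat
#' segments carrying only sensor noise. Ground truth (onset times, apnoea
#' intervals, the phase function) is returned exactly.
#'
#' @param spec a [resp_spec()].
#' @param duration signal duration in seconds (> 60).
#' @param fs sampling rate in Hz (>= 25); the clinical impedance
#'   pneumography rate is 62.5 Hz.
#' @param seed integer RNG seed.
#' @return a list: `ip` ([time_series()]), `breath_times` (onset seconds),
#'   `apnoeas` (data.frame `start`, `end`), `cycles` (data.frame `onset`,
#'   `dur`), `phase_fn` (vectorised time -> phase in `[0, 2*pi)`, `NA` during
#'   apnoea).
#' @export
gen_respiration <- function(spec = resp_spec(), duration, fs = 62.5,
                            seed = 1) {
  stopifnot(inherits(spec, "resp_spec"))
  if (duration <= 60) stop("`duration` must exceed 60 s")
  if (fs < 25) stop("`fs` must be >= 25 Hz")
  with_seed(seed, {
    n_apn <- round(spec$apnoea_rate * duration / 3600)
    margin <- 30
    if (n_apn > 0 &&
        n_apn * (spec$apnoea_duration + margin) > duration - 2 * margin) {
      stop("apnoea_rate x duration implies overlapping apnoeas")
    }
    apn_starts <- numeric(0)
    if (n_apn > 0) {
      usable <- duration - 2 * margin
      block <- usable / n_apn
      slack <- block - spec$apnoea_duration - margin
      apn_starts <- margin + (seq_len(n_apn) - 1) * block +
        stats::runif(n_apn, 0, max(slack, 0))
    }

    mean_T <- 60 / spec$rate
    sd_T <- 60 * spec$rate_sd / spec$rate^2
    onsets <- durs <- numeric(0)
    apn_true <- matrix(numeric(0), ncol = 2)
    t <- 0
    apn_i <- 1L
    while (t < duration) {
      T_k <- min(max(mean_T + stats::rnorm(1, 0, sd_T), 60 / 90), 60 / 20)
      if (apn_i <= n_apn && t + T_k > apn_starts[apn_i]) {
        # breathing pauses here; flat until the apnoea interval ends
        apn_end <- apn_starts[apn_i] + spec$apnoea_duration
        apn_true <- rbind(apn_true, c(t, apn_end))
        t <- apn_end
        apn_i <- apn_i + 1L
        next
      }
      if (t + T_k > duration) break
      onsets <- c(onsets, t)
      durs <- c(durs, T_k)
      t <- t + T_k
    }

    tt <- (seq_len(round(duration * fs)) - 1) / fs
    ci <- findInterval(tt, onsets)
    theta <- rep(NA_real_, length(tt))
    ok <- ci > 0
    theta[ok] <- (tt[ok] - onsets[ci[ok]]) / durs[ci[ok]]
    x <- breath_amplitude(theta, spec$insp_frac)
    x <- x + spec$cardiac_amp * sin(2 * pi * spec$cardiac_hz * tt) +
      stats::rnorm(length(tt), 0, spec$noise_sd)

    list(
      ip = time_series(x, fs = fs, labels = "IP"),
      breath_times = onsets,
      apnoeas = data.frame(start = apn_true[, 1], end = apn_true[, 2]),
      cycles = data.frame(onset = onsets, dur = durs),
      phase_fn = make_phase_fn(onsets, durs)
    )
  })
}

pink_noise <- function(n, fs, ncol = 1) {
  nfft <- stats::nextn(n, c(2, 3, 5))
  w <- matrix(stats::rnorm(nfft * ncol), nfft, ncol)
  f <- abs(c(seq(0, floor(nfft / 2)), seq(-ceiling(nfft / 2) + 1, -1))) *
    fs / nfft
  g <- 1 / sqrt(pmax(f, 0.1))
  g[1] <- 0
  x <- Re(stats::mvfft(stats::mvfft(w) * g, inverse = TRUE)) / nfft
  x <- x[seq_len(n), , drop = FALSE]
  scale(x, center = TRUE, scale = apply(x, 2, stats::sd))[, , drop = FALSE]
}

#' Generate EEG with respiratory phase-amplitude coupling
#'
#' Designated channels carry a band-limited noise carrier whose instantaneous
#' amplitude is proportional to `1 + m * cos(phase(t + tau) - phi0)`; all
#' channels carry a broadband 1/f (pink) background. Non-designated channels
#' carry the same carrier without modulation (m = 0). During apnoea (phase
#' undefined) the modulator is 1.
#'
#' @param phase_fn respiratory phase function (time -> radians), e.g. from
#'   [gen_respiration()] or [phase_function()].
#' @param spec a [coupling_spec()].
#' @param duration seconds; should match the respiration signal.
#' @param fs sampling rate in Hz; must be at least twice the carrier band's
#'   upper edge. The clinical EEG rate is 2000 Hz.
#' @param labels channel names to generate.
#' @param carrier_sd,background_sd SD of carrier and pink background.
#' @param seed integer RNG seed.
#' @return a [time_series()] of the generated EEG.
#' @export
gen_coupled_eeg <- function(phase_fn, spec = coupling_spec(), duration,
                            fs = 2000, labels = EEG_CHANNELS,
                            carrier_sd = 1, background_sd = 1, seed = 1) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (fs < 2 * spec$band[2]) stop("`fs` must be >= twice the band upper edge")
  with_seed(seed, {
    n <- round(duration * fs)
    tt <- (seq_len(n) - 1) / fs
    ph <- phase_fn(tt + spec$tau)
    cyc <- 2 * pi / stats::median(diff(tt[which(diff(ph) < -pi) + 1]),
                                  na.rm = TRUE)
    if (is.finite(cyc) && abs(spec$tau) > cyc) {
      warning("|tau| exceeds one respiratory cycle; lag aliases in phase")
    }
    modv <- 1 + spec$m * cos(ph - spec$phi0)
    if (!is.null(spec$phase_gate)) {
      # raised-cosine gate: modulation waxes and wanes smoothly inside the
      # gated phase range and vanishes outside it
      lo <- spec$phase_gate[1]; hi <- spec$phase_gate[2]
      g <- numeric(length(ph))
      inside <- !is.na(ph) & ph >= lo & ph < hi
      g[inside] <- 0.5 * (1 - cos(2 * pi * (ph[inside] - lo) / (hi - lo)))
      modv <- 1 + spec$m * g * cos(ph - spec$phi0)
    }
    modv[is.na(ph)] <- 1

    bg <- background_sd * pink_noise(n, fs, length(labels))
    x <- matrix(0, n, length(labels))
    for (j in seq_along(labels)) {
      carrier <- fft_bandpass(stats::rnorm(n), fs, spec$band[1], spec$band[2])
      carrier <- carrier / stats::sd(carrier)
      mj <- if (labels[j] %in% spec$channels) modv else 1
      x[, j] <- bg[, j] + carrier_sd * carrier * mj
    }
    time_series(x, fs = fs, labels = labels)
  })
}

#' Generate a dual-device ECG pair with shared annotations
#'
#' Renders one R-peak train on two devices at different sampling rates, the
#' second shifted by a known clock offset, plus ~30 shared annotations whose
#' timestamps are jittered to emulate the trigger device's finite precision
#' (105 ms by default).
#'
#' @param duration seconds.
#' @param offset seconds to add to the vitals clock to obtain the EEG clock;
#'   `|offset|` must be below 30 s.
#' @param fs_a vitals-side ECG sampling rate (250 Hz clinical default).
#' @param fs_b EEG-side ECG sampling rate (2000 Hz clinical default).
#' @param n_annotations number of shared annotations.
#' @param jitter_sd SD in seconds of the annotation time differences between
#'   devices (split evenly between the two sides).
#' @param hr_bpm mean heart rate (neonatal default 150 bpm).
#' @param noise_sd additive noise SD on both ECG renderings.
#' @param seed integer RNG seed.
#' @return a list: `ecg_vitals`, `ecg_eeg` ([time_series()]),
#'   `annotations_vitals`, `annotations_eeg` ([annotation_set()]), and the
#'   ground-truth `offset`.
#' @export
gen_ecg_pair <- function(duration, offset = 0, fs_a = 250, fs_b = 2000,
                         n_annotations = 30, jitter_sd = 0.105, hr_bpm = 150,
                         noise_sd = 0.05, seed = 1) {
  if (abs(offset) >= 30) stop("|offset| must be below 30 s")
  with_seed(seed, {
    rr <- 60 / hr_bpm
    n_beats <- ceiling((duration + abs(offset) + 2) / rr) + 2
    beat_t <- cumsum(stats::rnorm(n_beats, rr, 0.15 * rr))
    beat_t <- beat_t[beat_t > 0.5]

    render <- function(fs, shift) {
      n <- round(duration * fs)
      x <- numeric(n)
      sigma <- 0.012
      for (b in beat_t + shift) {
        i0 <- max(1L, floor((b - 5 * sigma) * fs) + 1L)
        i1 <- min(n, ceiling((b + 5 * sigma) * fs) + 1L)
        if (i0 > n || i1 < 1L) next
        ti <- (i0:i1 - 1) / fs
        x[i0:i1] <- x[i0:i1] + exp(-(ti - b)^2 / (2 * sigma^2))
      }
      x + stats::rnorm(n, 0, noise_sd)
    }
    # The EEG device's clock reads (true time + offset); its recording starts
    # at EEG-clock time `offset`, so the samples carry the same events as the
    # vitals rendering while every EEG-side timestamp is shifted by `offset`.
    ecg_a <- render(fs_a, 0)
    ecg_b <- render(fs_b, 0)

    # annotations must leave +/- 10 s of ECG on both device clocks
    lo <- 11 + max(0, -offset)
    hi <- duration - 11 - max(0, offset)
    if (hi - lo < n_annotations) stop("duration too short for the annotations")
    u <- lo + (seq_len(n_annotations) - 0.5) / n_annotations * (hi - lo)
    ja <- stats::rnorm(n_annotations, 0, jitter_sd / sqrt(2))
    jb <- stats::rnorm(n_annotations, 0, jitter_sd / sqrt(2))
    ids <- sprintf("annot%02d", seq_len(n_annotations))
    list(
      ecg_vitals = time_series(ecg_a, fs = fs_a, labels = "ECG"),
      ecg_eeg = time_series(ecg_b, fs = fs_b, t0 = offset, labels = "ECG"),
      annotations_vitals = annotation_set(sort(u + ja),
                                          ids[order(u + ja)]),
      annotations_eeg = annotation_set(sort(u + offset + jb),
                                       ids[order(u + offset + jb)]),
      offset = offset
    )
  })
}

#' Generate a full synthetic recording bundle
#'
#' Assembles respiration, coupled EEG, a dual-device ECG pair and metadata
#' into the bundle structure consumed by [write_recording()] and the pipeline
#' stages. The EEG and IP start at the (vitals-relative) clock offset so that
#' synchronisation is exercised end to end.
#'
#' @param duration seconds.
#' @param rspec a [resp_spec()].
#' @param cspec a [coupling_spec()].
#' @param offset inter-device clock offset in seconds.
#' @param fs_eeg,fs_ip,fs_ecg_vitals sampling rates in Hz.
#' @param meta a [recording_meta()].
#' @param seed integer RNG seed.
#' @return a recording bundle list with an extra `truth` element (breath
#'   times, apnoea intervals, m, phi0, tau, offset).
#' @export
gen_recording <- function(duration = 300, rspec = resp_spec(),
                          cspec = coupling_spec(), offset = 0,
                          fs_eeg = 2000, fs_ip = 62.5, fs_ecg_vitals = 250,
                          meta = recording_meta("inf01", 34.5,
                                                "self-ventilating"),
                          seed = 1) {
  resp <- gen_respiration(rspec, duration, fs_ip, seed = seed)
  eeg <- gen_coupled_eeg(resp$phase_fn, cspec, duration, fs_eeg,
                         seed = seed + 1L)
  # EEG device clock = vitals clock + offset
  eeg$t0 <- offset
  pair <- gen_ecg_pair(duration, offset, fs_a = fs_ecg_vitals, fs_b = fs_eeg,
                       seed = seed + 2L)
  list(
    eeg = eeg,
    ecg_eeg = pair$ecg_eeg,
    ip = resp$ip,
    ecg_vitals = pair$ecg_vitals,
    annotations_eeg = pair$annotations_eeg,
    annotations_vitals = pair$annotations_vitals,
    meta = meta,
    truth = list(breath_times = resp$breath_times, apnoeas = resp$apnoeas,
                 m = cspec$m, phi0 = cspec$phi0, tau = cspec$tau,
                 offset = offset, phase_fn = resp$phase_fn)
  )
}

#' Generate a cohort table with a known coupling-to-apnoea-rate slope
#'
#' Per-recording coupling depth `m` is drawn uniformly from `m_range`; the
#' apnoea rate is a linear function of `m` with infant-level random
#' intercepts, covariate effects (PMA, ventilation mode, data length) of
#' configurable size, and Gaussian noise, truncated at zero.
#'
#' @param n_infants number of infants (>= 10); the study cohort is 68.
#' @param n_recordings total recordings (>= n_infants); the study has 104.
#' @param slope change in apnoea rate (events/h) per unit coupling.
#' @param intercept expected apnoea rate (events/h) at m = 0 and reference
#'   covariates.
#' @param m_range range of coupling depths.
#' @param infant_sd SD of the infant-level random intercept.
#' @param noise_sd residual SD of the apnoea rate.
#' @param pma_effect,length_effect effects per week of PMA (centred at 34.5)
#'   and per hour of data length (centred at 10 h).
#' @param vent_effect additive effects `c(low_flow, high_flow)` relative to
#'   self-ventilating.
#' @param seed integer RNG seed.
#' @return a `data.frame` (one row per recording) with columns
#'   `recording_id`, `infant_id`, `pac`, `apnoea_rate`, `data_length_hours`,
#'   `ventilation_mode`, `pma_weeks`, `caffeine`; ground-truth parameters are
#'   attached as attribute `"truth"`.
#' @export
gen_cohort <- function(n_infants = 68, n_recordings = 104, slope = -2.5,
                       intercept = 3, m_range = c(0.1, 0.6),
                       infant_sd = 0.7, noise_sd = 1.0,
                       pma_effect = 0, length_effect = 0,
                       vent_effect = c(0, 0), seed = 1) {
  if (n_infants < 10) stop("`n_infants` must be >= 10")
  if (n_recordings < n_infants) stop("need at least one recording per infant")
  with_seed(seed, {
    infants <- sprintf("inf%03d", seq_len(n_infants))
    extra <- sample(infants, n_recordings - n_infants, replace = TRUE)
    infant_id <- sort(c(infants, extra))
    b <- stats::rnorm(n_infants, 0, infant_sd)
    names(b) <- infants

    m <- stats::runif(n_recordings, m_range[1], m_range[2])
    pma <- pmin(pmax(stats::rnorm(n_recordings, 34.5, 2.6), 28), 42)
    vent <- sample(c("self-ventilating", "low-flow", "high-flow"),
                   n_recordings, replace = TRUE, prob = c(0.66, 0.13, 0.21))
    len <- pmin(pmax(abs(stats::rnorm(n_recordings, 9.5, 9.9)), 0.5), 24)
    caffeine <- stats::runif(n_recordings) < 0.48

    mu <- intercept + slope * m +
      pma_effect * (pma - 34.5) + length_effect * (len - 10) +
      ifelse(vent == "low-flow", vent_effect[1],
             ifelse(vent == "high-flow", vent_effect[2], 0)) +
      b[infant_id]
    if (any(mu < 0)) {
      warning("expected apnoea rate negative for some recordings; ",
              "rates clipped at 0")
    }
    rate <- pmax(mu + stats::rnorm(n_recordings, 0, noise_sd), 0)

    out <- data.frame(
      recording_id = sprintf("rec%03d", seq_len(n_recordings)),
      infant_id = infant_id,
      pac = m,
      apnoea_rate = rate,
      data_length_hours = len,
      ventilation_mode = vent,
      pma_weeks = pma,
      caffeine = caffeine,
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- list(slope = slope, intercept = intercept,
                               infant_sd = infant_sd, noise_sd = noise_sd,
                               m = m, random_intercepts = b)
    out
  })
}
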