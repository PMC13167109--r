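# Shared reduced-scale fixtures: EEG is generated at 50-80 Hz rather than the
# clinical 2 kHz (the carrier bands under test lie below 25 Hz) and
# recordings are minutes rather than hours, keeping the suite fast while
# exercising the identical code paths.

quiet_resp <- function(duration = 240, seed = 1, rate = 54, rate_sd = 5,
                       noise_sd = 0.05, apnoea_rate = 0, ...) {
  gen_respiration(
    resp_spec(rate = rate, rate_sd = rate_sd, apnoea_rate = apnoea_rate,
              noise_sd = noise_sd, ...),
    duration = duration, fs = 62.5, seed = seed
  )
}

# A coupled IP + EEG pair with its detected breath record and epoch set.
coupled_setup <- function(seed = 1, m = 0.5, tau = 0, phi0 = 0,
                          band = c(4, 8), phase_gate = NULL, duration = 240,
                          fs_eeg = 50, channels = "FCz",
                          labels = channels, rate = 54, noise_sd = 0.05) {
  resp <- quiet_resp(duration, seed = seed, rate = rate, noise_sd = noise_sd)
  cs <- coupling_spec(band = band, m = m, phi0 = phi0, tau = tau,
                      channels = channels, phase_gate = phase_gate)
  eeg <- gen_coupled_eeg(resp$phase_fn, cs, duration, fs = fs_eeg,
                         labels = labels, seed = seed + 10000L)
  ipf <- filter_ip(resp$ip)
  record <- detect_breaths(ipf)
  list(resp = resp, eeg = eeg, ipf = ipf, record = record,
       epochs = reject_epochs(make_epochs(ipf, eeg), record))
}

# Minimal hand-built coupling_result for arithmetic-level tests.
fake_coupling_result <- function(coherence, f1_grid, f2_grid, channels) {
  structure(
    list(f1_grid = f1_grid, f2_grid = f2_grid, channels = channels,
         coherency = coherence * (1 + 0i), coherence = coherence,
         delta_f = diff(f1_grid)[1], n_epochs = 10),
    class = "coupling_result"
  )
}

expect_no_na <- function(x) expect_false(anyNA(x))
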