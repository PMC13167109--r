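# respac

Cortico-respiratory phase-amplitude coupling in neonatal EEG, and its
relationship to apnoea.

## What it does

In newborn infants, apnoea (cessation of breathing) is common and is usually
attributed to immature brainstem respiratory control. A complementary
question is whether the *cortex* participates: is the amplitude of cortical
oscillations modulated by the phase of the respiratory cycle, and does
stronger coupling go with fewer apnoeas? `respac` implements the full
analysis pipeline for simultaneous EEG and impedance-pneumography (IP)
recordings:

1. **Breath & apnoea detection** — zero-phase 0.1–2 Hz IP filtering, an
   adaptive amplitude threshold (0.4 × running SD over the preceding 15
   breaths) with trough-anchored onsets, a pluggable classifier separating
   apnoeas from low-amplitude breathing among inter-breath intervals ≥ 15 s,
   and an events-per-hour apnoea rate.
2. **Clock synchronisation** — shared annotations matched between devices,
   refined by cross-correlating ±10 s ECG windows recorded on both devices;
   the offset is the median over annotations, with QC exclusion when the
   annotation SD exceeds 1 s or the ECG-refined SD exceeds 0.1 s.
3. **Phase-amplitude coupling (PAC)** — cross-frequency coherence between
   the IP signal at modulation frequency f1 and the Hilbert envelope of the
   EEG band-passed at carrier f2 (bandwidth = f1), over Hann-tapered 4-s
   epochs with 50% overlap (0.25 Hz resolution) and artifact rejection:

       C(f1,f2) = |Σₙ Xₙ(f1) · Yₙ(f1,f2)*| / √(Σₙ|Xₙ|² · Σₙ|Yₙ|²)

4. **Timing within the breath** — PAC at 50 equally spaced phase points per
   respiratory cycle using 2/3-s windows, and breath-locked time-frequency
   amplitude maps.
5. **Directionality** — a cross-frequency phase-slope index Ψ over a 1 Hz
   window (4 × the frequency resolution) along the modulation-frequency
   axis; positive Ψ = EEG amplitude leads respiration (sign calibrated on
   known-lag synthetic data).
6. **Significance** — epoch-shuffle surrogates (derangement of the EEG epoch
   order; within-epoch structure untouched), group-level dependent t-tests,
   Benjamini–Hochberg FDR (alpha 0.001 for coherence, 0.05 for Ψ).
7. **Association with apnoea** — `apnoea_rate ~ pac + data_length +
   ventilation_mode + pma + (1 | infant)` via `lme4`, reporting the PAC
   slope's t on residual dof, two-sided p, and partial correlation
   ρ = t/√(t² + dof), plus a covariate-adjusted scatter for plotting.

A synthetic-data module (`gen_respiration()`, `gen_coupled_eeg()`,
`gen_ecg_pair()`, `gen_cohort()`, `gen_recording()`) generates signals with
exact ground truth — breath times, apnoea intervals, coupling depth m,
preferred phase, envelope lag, inter-device clock offset, cohort-level
slopes — so every stage is verifiable without access to clinical recordings.

## Worked example

```r
library(respac)

# a 5-minute synthetic recording: theta-band coupling at depth 0.5 on FCz/Cz,
# EEG envelope leading respiration by 300 ms, devices offset by 2.5 s
rec <- gen_recording(
  duration = 300, offset = 2.5, fs_eeg = 64,
  rspec = resp_spec(rate = 54, apnoea_rate = 0),
  cspec = coupling_spec(band = c(4, 8), m = 0.5, tau = 0.3),
  seed = 42
)
res <- analyse_recording(rec, f2_grid = seq(0.5, 12, 0.25),
                         channels = "FCz", seed = 1)
res$sync
#> <sync_result> offset = 2.5001 s over 30 annotations (annot SD 0.115 s, ECG SD 0.0007 s)
res$record
#> <breath_record> 270 breaths over 5.0 min; 0 long IBI(s) (0 apnoea)
res$spectrum
#> <coupling_result> 8 x 47 (f1 x f2) grid, 1 channel(s), N = 148 epochs, delta_f = 0.25 Hz

# theta-band coupling against its epoch-shuffled surrogate
band_average(res$spectrum, list(theta = c(4, 8)))
#>          FCz
#> theta 0.1314
band_average(res$surrogate, list(theta = c(4, 8)))
#>          FCz
#> theta 0.0787

# directionality at the respiratory frequency, over the coupled band
psi <- phase_slope_index(res$spectrum)
in_band <- res$spectrum$f2_grid >= 4 & res$spectrum$f2_grid <= 8
mean(psi$psi[res$spectrum$f1_grid == res$resp_f1, in_band, "FCz"],
     na.rm = TRUE)
#> [1] 0.0207   # positive: EEG amplitude leads respiration
```

The synchroniser recovers the 2.5 s inter-device offset to sub-millisecond
accuracy; the theta-band coupling (0.131, averaged over all grid cells in
the band, most of which are off the respiratory frequency) stands well above
its epoch-shuffled surrogate (0.079, close to the √(π/4)/√N small-sample
bias at N = 148); and the phase-slope index at the respiratory frequency is
positive, recovering the direction of the injected 300 ms envelope lead.

A command-line wrapper over the same functions lives at
`inst/cli/respac.R` (subcommands `simulate`, `sync`, `breaths`, `pac`,
`cycle-pac`, `psi`, `stats`, `associate`, each taking `--config`, `--seed`,
`--out`).

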