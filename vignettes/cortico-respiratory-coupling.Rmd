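---
title: "Quantifying cortico-respiratory coupling in neonatal recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortico-respiratory coupling in neonatal recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respac)
```

# The problem

In newborn infants — especially preterm infants — breathing pauses (apnoeas)
are common and potentially harmful. Classical accounts attribute apnoea of
prematurity to immaturity of brainstem respiratory centres; whether *cortical*
activity participates in neonatal respiratory control is an open question.
One way to probe it non-invasively is to ask whether the amplitude of
cortical oscillations, recorded with EEG, is systematically modulated by the
phase of the respiratory cycle, recorded with impedance pneumography (IP).
That statistical dependence is phase-amplitude coupling (PAC). `respac`
implements a complete, testable pipeline for this question: breath detection,
inter-device clock synchronisation, PAC estimation, its timing within the
breath, its directionality, surrogate-based significance, and a cohort-level
mixed-model association between coupling strength and apnoea rate.

# The coupling estimator

PAC is quantified as **cross-frequency coherence**. The signals are segmented
into epochs of $L = 4$ s with 50% overlap, giving a spectral resolution of
$\Delta f = 1/L = 0.25$ Hz. For a modulation frequency $f_1$ (on the
$\Delta f$ grid, typically at the infant's mean respiratory frequency) and an
EEG carrier frequency $f_2$:

* $X_n(f_1)$ is the Hann-tapered spectral coefficient of the filtered IP
  signal in epoch $n$;
* $Y_n(f_1, f_2)$ is the coefficient — also at $f_1$ — of the *instantaneous
  amplitude* of the EEG, obtained as the magnitude of the analytic signal
  after band-pass filtering around $f_2$ with bandwidth equal to $f_1$
  (so at $f_1 = 5$ Hz the filter at $f_2$ is 5 Hz wide);
* the complex coherency and its magnitude (the PAC coherence) are

$$
\tilde C(f_1,f_2) \;=\;
  \frac{\sum_{n=1}^{N} X_n(f_1)\, Y_n(f_1,f_2)^{*}}
       {\sqrt{\sum_n |X_n(f_1)|^2 \; \sum_n |Y_n(f_1,f_2)|^2}},
\qquad C = |\tilde C| \in [0, 1].
$$

For independent signals the estimator is biased upwards by finite $N$:
$\mathbb E[C] \approx \sqrt{\pi/4}/\sqrt{N}$. The test suite verifies this
bias law by Monte-Carlo at $N \in \{16, 64, 256\}$; all significance
statements are made against epoch-shuffle surrogates rather than against
zero.

Two numerical details matter and are easy to get wrong:

* **Taper-weighted demeaning.** An amplitude envelope is positive-valued, so
  its tapered DFT leaks a large DC term into the lowest bins and inflates
  coherence at small $f_1$. Every tapered coefficient here subtracts the
  taper-weighted epoch mean first, which removes the leak exactly for a
  constant offset.
* **Zero-phase filtering.** All band-pass filters (the 0.1–2 Hz IP filter
  and every envelope filter) are frequency-sampling filters with
  raised-cosine transitions (width 25% of the bandwidth; pass-band edges
  clipped at 0.25 Hz and Nyquist), applied in the frequency domain. They are
  zero-phase by construction, which the breath-onset timing and the
  directionality analysis both rely on; sub-hertz bandwidths make
  equivalent FIR designs impractically long.

## Epoch rejection

Epochs are discarded, in order, when they (1) contain fewer than three
detected breaths or overlap an interval discarded as noise/shallow breathing,
(2) have a standard deviation above three times the mean *or* the median of
all epochs' SDs (checked separately for IP and for each EEG channel), or
(3) contain an absolute value above ten times the mean or median of the epoch
SDs. The mean-or-median disjunction is deliberately conservative (either
bound suffices); `reject_epochs(centre =)` switches to a single bound.

# Breath and apnoea identification

The IP signal is band-passed to 0.1–2 Hz (respiration in neonates runs at
roughly 0.7–1 Hz; the upper edge excludes cardiac rates of ~2–3 Hz) and
breaths are detected by an adaptive amplitude threshold: a breath is marked
where the signal crosses, rising from below, 0.4 times the SD of the signal
over the window spanning the 15 previously detected breaths (the global
record SD bootstraps the first 15, where the rule is otherwise undefined).
Because the threshold is SD-relative, detection is invariant to overall
signal scaling. Each detected crossing is then refined backwards to the
preceding trough: the crossing sits a fixed fraction up the inspiratory rise
and therefore lags the start of inspiration by ~0.1–0.2 s, which at neonatal
breathing rates is nearly a radian of respiratory phase; the trough is the
inspiration onset and anchors phase 0 of all breath-locked analyses.
`detect_breaths(refine = "crossing")` keeps the raw crossing times.

Inter-breath intervals (IBIs) of 15 s or more are candidate apnoeas. A
pluggable classifier separates true apnoeas from low-amplitude or noisy
breathing; the default is a two-feature rule (within-interval SD relative to
surrounding breathing SD below 0.3, and under half of the spectral power in
the 0.3–2 Hz respiratory band), chosen because a genuine apnoea is both
near-flat and aperiodic, while shallow breathing keeps its periodicity. Any
model with the same features-to-labels interface can replace it. Intervals
labelled noise-or-shallow are discarded from *all* further analysis: they
count neither toward the apnoea rate nor toward analysis epochs. The apnoea
rate divides apnoea events by analysed hours (dropout gaps excluded, window
capped at 24 h); we count events rather than event-time, since a rate per
hour is the clinically reported quantity.

# Timing within the respiratory cycle

Coupling is resolved at 50 equally spaced phase points per breath. At each
phase point a window of 2/3 s — sub-cycle, so temporal changes appear within
the breath — is gathered from every analysable breath, both windows are
resampled onto a common grid, Hann-tapered, taper-demeaned, and the
coherence across breaths between the IP and band-envelope coefficients at
the window's first non-zero bin is the time-resolved PAC. "2/3 s" is read as
two-thirds of a second (0.667 s); the window length is a plain argument, so
a 2–3 s reading is one keystroke away, but sub-cycle windows are the only
reading under which within-cycle changes are observable at ~1 s breath
periods.

A property worth knowing when interpreting these curves: the estimator
responds to *within-window modulator variation*, not to the modulator's
instantaneous value. A constant-depth sinusoidal modulator therefore does not
produce a flat profile (its within-window variation is proportional to
$|\sin\theta|$); what the curves localise reliably is where coupling is
present versus absent, which is what the phase-gated recovery test asserts.

# Directionality

Whether the EEG envelope leads or trails respiration is estimated with a
cross-frequency phase-slope index. A fixed time lag $\tau$ between envelope
and respiration makes the coherency phase change linearly across the
*modulation* frequency: $\arg \tilde C(f_1, f_2)$ has slope $-2\pi\tau$ in
$f_1$. The index accumulates the imaginary parts of conjugate products of
coherencies at neighbouring modulation frequencies within a window of width
$\beta$ centred on $f_1$:

$$
\Psi(f_1, f_2) \;=\; -\,\mathrm{imag}
  \sum_{f \in [f_1 - \beta/2,\; f_1 + \beta/2]}
  \tilde C^{*}(f, f_2)\; \tilde C(f + \Delta f, f_2),
$$

with $\beta = 1$ Hz, i.e. four times the 0.25 Hz resolution (four conjugate
products per window). The slope must run along the modulation axis: the lag
between an envelope and respiration does not depend on which carrier the
envelope was extracted from, so the coherency phase is constant along $f_2$
and a slope taken along the carrier axis would vanish in expectation for any
pure lag. The overall sign is a convention (it depends on the conjugation
order); it is calibrated on synthetic data with a known lag and fixed so that
**positive $\Psi$ means the EEG amplitude leads respiration**. A calibration
test generates envelope-leading data and asserts the sign. Cells whose
$\beta$ window would leave the $f_1$ grid are reported missing rather than
estimated from a truncated window.

When coupling is present but lag-free, $\Psi$ has zero expectation but its
sampling noise scales with the (large) coherency magnitude, so a
per-recording surrogate band — whose coherencies sit at the no-coupling bias
level — is not a valid null for it. Directionality inference therefore runs
through the same group-level paired comparison against surrogates as the
coherence maps.

# Surrogate statistics

The null hypothesis — no epoch-wise alignment between respiration and the
EEG envelope — is materialised by permuting the *order* of the EEG epochs
with a derangement (no epoch keeps its true partner; sampled by
shuffle-until-valid, capped at 1000 tries) while leaving the respiration
epoch order and all within-epoch samples untouched. Each signal's own
spectra are exactly preserved; only the cross-signal pairing is destroyed.
One surrogate spectrum is computed per recording (more can be averaged;
the count and seed are recorded). At the group level, true and surrogate
spectra are compared cell-by-cell with two-sided dependent t-tests across
recordings (zero-variance cells are degenerate and get p = 1), and
significance is controlled with Benjamini–Hochberg FDR pooled over all grid
cells and channels — alpha 0.001 for coherence maps and 0.05 for phase-slope
maps. Two-sided tests and BH (rather than BY) are the package's choices
where the procedure leaves them open.

# The coupling–apnoea association

One row per recording: PAC (mean coherence over the FDR-significant
delta+theta cells of channels FCz and Cz, pooled), the apnoea rate per hour,
the data length used for the rate, ventilation mode, postmenstrual age (PMA)
and infant id. The model is

```
apnoea_rate ~ pac + data_length_hours + ventilation_mode + pma_weeks
              + (1 | infant_id)
```

fitted with `lme4`. Self-ventilating is the reference ventilation level (the
most common category). The PAC slope is reported with its t statistic on
residual degrees of freedom $n - p$ (104 recordings with intercept, PAC,
length, two ventilation contrasts and PMA give $t(98)$), a two-sided p, and
the partial correlation $\rho = t/\sqrt{t^2 + \mathrm{dof}}$. Mixed-model
degrees of freedom are not uniquely defined; residual dof is the convention
that matches the reported design and is stated wherever the numbers are
shown. A singular random-effect fit, or a cohort with fewer than two
repeatedly measured infants, falls back to ordinary least squares with a
flag. For visualisation, `adjusted_response()` refits without the random
effect and holds the non-PAC covariates at their means (reference level for
ventilation), returning the covariate-adjusted scatter and its best-fit
line.

# What the synthetic data emulate — and what they do not

The generators produce: quasi-periodic respiration (default 50 ± 5
breaths/min) as asymmetric raised-cosine cycles (inspiration 40% of the
cycle, so inspiratory and expiratory halves are distinguishable), with
near-flat apnoea insertions of at least 15 s and exact ground-truth onsets;
EEG as per-channel pink-noise background plus a band-limited noise carrier
whose instantaneous amplitude is $1 + m\cos(\phi(t+\tau) - \phi_0)$ on
designated channels (modulation rides on respiratory *phase*, not time, so
rate variability transfers correctly); an optional raised-cosine phase gate
confining modulation to part of the cycle (a hard-edged gate would inject
discontinuity transients that dominate time-resolved coherence); dual-device
ECG renderings of one R-peak train at 250 and 2000 Hz with a known clock
offset and ~30 shared annotations jittered to 105 ms precision; and cohorts
of 104 recordings from 68 infants with coupling depths $m \sim U(0.1, 0.6)$
(observed depths are not reported anywhere we could anchor to, so this range
is a documented free choice) and an apnoea rate linear in $m$ with
infant-level random intercepts.

They do **not** emulate sleep-state cycling, realistic EEG
microstructure (spindles, burst suppression), realistic ECG morphology,
movement artifact structure, or clock drift (the pipeline applies a single
constant offset, matching the synchronisation model). Passing tests
demonstrate that the estimators recover known structure under this model;
they cannot certify performance on features the model lacks.

Other defaults follow the recording setup the package targets: EEG at 2 kHz
on eight channels (Cz, CPz, C3, C4, Oz, FCz, T3, T4) plus an EEG-side ECG,
IP at 62.5 Hz, vitals-side ECG at 250 Hz. The EEG is analysed in its
recording reference (Fz); no re-referencing is applied. Synchronisation
uses all matched annotations without outlier trimming before the median —
the median is already robust, and the QC thresholds (exclude when the
annotation-difference SD exceeds 1 s or the ECG-refined SD exceeds 0.1 s)
catch pathological recordings.

# Validation problem sizes

The test suite and `scripts/acceptance.R` run the full pipeline on reduced
problem sizes chosen so every stage is exercised in minutes: EEG generated
at 50–80 Hz (the carriers of interest lie below 25 Hz), recordings of 3–5
minutes (≈ 120–150 retained epochs), carrier grids trimmed to the bands
under test, and 12–100 Monte-Carlo repetitions per property. The clinical
defaults (2 kHz, hours) remain the generator defaults; nothing in the
implementation depends on the reduced sizes.

# Known limitations

* The default long-IBI classifier is a transparent two-feature rule; on real
  IP data a trained model (the interface accepts any) should replace it.
* PSI is a directionality *statistic*, not a causal claim; low
  signal-to-noise or asymmetric preprocessing can bias it.
* Coherence-based PAC assumes the modulation is stable across epochs within
  a recording; strongly non-stationary coupling dilutes the estimate.
* Cycle-resolved PAC blurs phase by roughly ± window/(2·cycle) of a cycle;
  at 1 s breaths and 2/3 s windows features closer than ~±2 rad mix.
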