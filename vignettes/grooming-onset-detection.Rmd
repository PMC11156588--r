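---
title: "Methods: closed-loop grooming-onset detection from orbitofrontal LFP"
author: "groomloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop grooming-onset detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms and numerical choices
behind `groomloop`, in the order the data flow through the pipeline, and
states explicitly which decisions were genuinely open and how they were
resolved.

## 1. The biomarker and its synthetic emulation

The system targets a low-frequency (delta, 1–4 Hz) power ramp in lateral
orbitofrontal LFP that begins on the order of one second before a
grooming bout starts and peaks near 2 Hz. The synthetic generator
(`behaviorModel`, `biomarkerModel`, `simulateBehavior`, `simulateLfp`)
emulates exactly the statistical structure the detection method assumes:

* **Behavior**: grooming onsets follow a gamma-renewal process (shape 2)
  at 12.9 bouts per 10 min; a renewal rather than Poisson process avoids
  unrealistically short inter-bout intervals, since bouts cannot overlap.
  Bout durations are log-normal (`meanlog = log(4) - 0.125`,
  `sdlog = 0.5`; mean 4 s, truncated below 1 s), chosen so that the total
  early-detection-period time per 10-min session —
  `bouts x (2 + duration/2)` ≈ 50 s — matches the published session
  statistics. Generated annotations always satisfy the bout scoring rules
  (interruptions < 1 s merge; phases < 1 s are discarded), so
  `cleanGroomingEvents` is the identity on them. Non-grooming time is
  tiled by a semi-Markov chain over walking / rearing / resting /
  scratching / other with exponential dwells — enough structure to supply
  labeled negative windows and "no preceding motor behavior" exclusions,
  and nothing more.
* **LFP**: per channel, unit-variance 1/f Gaussian background plus, around
  each onset, a narrowband stochastic oscillation (Gaussian spectral
  shape, 2 ± 1 Hz) whose amplitude ramps linearly from zero starting
  0.9 s before onset, holds through 0.5 s after onset and is released
  with a 0.1-s cosine taper. Channels share event timing but have
  independent noise and independent oscillation realizations; per-channel
  gains vary by ±20%. The oscillation's slow chance envelope is leveled
  (local 1-s power normalized) before the deterministic ramp is applied,
  so the event-to-event burst strength is set by the ramp, not by the
  carrier's own amplitude modulation — without this, a few percent of
  events carry almost no burst no matter how large the nominal amplitude,
  which contradicts the reliable per-event ramp the biomarker analyses
  assume.
* **Amplitude calibration**: `rampAmplitudeRel` (default 8) is the peak
  oscillation power relative to the background power in the oscillation
  band. From the linear ramp, the mean-square envelope over the 1-s
  pregrooming window is 0.3, so the default puts the measured
  pregrooming-vs-rest band-power ratio near 3.5 — the clearly-detectable
  regime the end-to-end checks prescribe. The default simulation rate is
  1000 Hz (tests and the acceptance script use 250 Hz); the biomarker
  lives below 13 Hz, and the nominal 20-kHz acquisition rate matters only
  for the reduction-ratio bookkeeping, which is always computed against
  32 x 20 kHz x 1 s.
* **Stimulation response** (`stimulationResponseModel`): a grooming bout
  whose pre-onset window `[onset - 2 s, onset]` overlaps any stimulation
  interval is removed with probability 0.7. This is a deliberately simple
  in-silico device — no mechanistic claim — that lets the full
  OFF/CL/RANDOM protocol produce behavioral endpoints. Stimulation is
  applied post hoc to the annotation; the suppressed bout's pre-onset LFP
  ramp remains in the signal, modeling an initiation that was blocked.

**What passing tests show, and what they do not.** The generator
reproduces the timing statistics, the spectral shape of the biomarker and
the labeling geometry. It does not emulate nonstationary background
(movement artifacts, volume conduction, electrode drift within a
session), correlated noise across electrodes, behavior-specific spectral
signatures of walking or scratching, or delta power persisting through
the grooming bout itself. Results on synthetic sessions therefore bound
what the pipeline can do under its own assumptions; they do not certify
in-vivo performance.

## 2. Offline spectral characterization

* **Preprocessing** (`preprocessLowfreq`): sample-rate reduction by 40
  (20 kHz → 500 Hz) and a tenth-order Butterworth low-pass at 10 Hz. The
  filter is applied as the Butterworth *magnitude* response in the
  frequency domain — exactly zero-phase and numerically stable where a
  time-domain order-10 recursion at a normalized cutoff of 0.04 is
  fragile — and doubles as the anti-alias filter, after which the signal
  is subsampled.
* **Single-window PSD** (`computePsd`): Hann-tapered periodogram of one
  1-s window, zero-padded to a 0.25-Hz grid. Single 1-s windows preclude
  Welch averaging, and the 1–10 Hz filterbank needs a fine grid. The mean
  is removed per window (offset invariance), and the one-sided density is
  normalized so the discrete Parseval relation holds to numerical
  precision.
* **Event spectrograms** (`eventSpectrogram`): generalized Morse wavelet
  with asymmetry `gamma = 3` and time-bandwidth product 60 (so
  `beta = 20`), implemented as analytic frequency-domain filters
  (peak-normalized), on a logarithmic grid 0.5–20 Hz at 16 voices per
  octave; power is averaged across channels and events over ±4 s around
  onset.
* **Rising point** (`detectRisingPoint`): the published analyses report
  where the 1.5–4 Hz power curve begins its pre-onset rise but not how
  that point was computed. The package's operationalization: baseline =
  curve mean over [−4, −2] s; threshold = baseline + 20% of
  (peak − baseline); rising point = earliest time in [−4, 0] from which
  the curve stays above threshold through onset. The 20% fraction is a
  configurable parameter; the rule is validated by parameter recovery —
  on sessions generated with the ramp start moved to −1.0 s, the
  session-averaged estimates recover −1.0 within 0.3 s mean absolute
  error, and the peak-frequency estimate falls in the published
  interquartile envelope (both recomputed by the test suite). A flat
  curve returns `NA` ("no ramp"), never a fabricated time.
* The "no preceding motor behavior" exclusion for the band-power contrast
  is fixed at 3 s before onset (the exclusion is published, the window is
  not; 3 s covers the 2-s labeling window plus the 1-s analysis window).

## 3. Feature reduction

The filterbank warps frequency as
`u(f) = sign(f - F) log(1 + |f - F| / w)` (w = 1 Hz) and places the
`M = 7` centers uniformly in `u` between the band edges, so center
density is maximal at the principal frequency `F = 2.5` Hz and spacing
grows geometrically away from it on both sides; each triangle spans its
neighboring centers (adjacent filters cross at half height). Filter
energies are log-transformed before the cosine transform — whether the
original implementation used logs is unstated; the log is standard
cepstral practice and makes coefficients 2..M exactly invariant to
amplitude scale (a property the test suite asserts) — and `logEnergies`
is exposed as a switch. The decorrelating transform is the orthonormal
DCT-II, checked against a direct O(M²) cosine-sum oracle.

The `P = 5` temporal iterations are read as the five most recent sliding
windows (200-ms shift, 1.8 s of history) rather than five subsegments of
one window, matching the −2 s labeling geometry. Where the source
material gives both "seven filters / M = 7" and an "N = 5" in the filter
definition, the package follows M = 7 filters and P = 5 iterations; the
upper band edge (10 ± 3 Hz across subjects) is the configurable
`f_B_hz`.

## 4. Classification and voting

Each electrode gets its own 35-16-8-2 network (logistic hidden units,
softmax output, cross-entropy loss, full-batch Adam at learning rate
0.01, early stopping on a 20% validation split with patience 30) — layer
widths, optimizer and epochs are unpublished, so they are configuration
with these defaults. Two practical choices matter:

* **Seeded multi-restart** (default 3): small networks on a few hundred
  windows occasionally stall in a one-class minimum; the fit with the
  lowest validation loss is kept. Training remains bit-deterministic
  given the seed.
* **Ties resolve negative**: an exact 0.5/0.5 output scores "other", and
  a vote of exactly 50% of electrodes does not trigger — the conservative
  reading of a strict ">50%" stimulation policy.

Features are z-scored with statistics estimated on the training set only
and stored in the model; a test asserts the normalization is applied
exactly once at prediction.

**Training-window placement.** Pregrooming windows are drawn from the
2-s pre-onset labeling interval at onset and onset − 0.2 s. Under the
generator's own physiology the ramp begins only 0.9 s before onset, so
1-s windows ending earlier than ~0.4 s before onset contain almost no
biomarker; including them as positive examples measurably degraded every
classifier tried (including a linear-discriminant reference) toward
chance. Two placements per bout also reproduce the published dataset
density (a minimum of 100 windows gathered from five 1-h sessions is one
to two windows per bout). Negatives are sampled from annotated
non-grooming behavior at least 2.5 s from any bout, in equal number. The
pooled windows are shuffled and split 70/30 by seed.

## 5. The streaming engine

Decisions live on a rigid 200-ms grid. A decision at time t needs
`window + (P-1) x shift = 1.8 s` of signal history; warmup is therefore
relative to the available recording, not to trial boundaries — a
recording with ~2 s of pre-roll (session time starting below zero, as a
continuously acquired session provides) yields the full 10,800-decision
grid over a 12 x 3-min schedule. In CL trials a triggered decision emits
a 4-s stimulation and decisions pause until it ends (exactly 20 grid
bins per stimulation); in OFF and RANDOM trials decisions are still
computed and logged for offline scoring but never stimulate. RANDOM
trials carry as many events as the immediately preceding CL trial,
placed by the order-statistics construction (sorted uniforms plus
accumulated event lengths) — exactly uniform over non-overlapping
configurations, and rejection-free. The published continuous protocol
text is internally inconsistent ("ten interleaved" vs "five interleaved"
trials in a 30-min session); 5 OFF + 5 ON of 3 min is the arithmetic
resolution used.

## 6. Scoring

Early-detection periods are `[onset - 2, onset + duration/2]`, clipped
to the session. Scoring is bin-level: positive-in-Ep = TP,
negative-in-Ep = FN, and outside Ep and outside grooming, positive = FP
and negative = TN. Two deliberate conventions:

* **Bin-level FN.** The published FN definition is event-level ("missed
  grooming events") while TP/TN/FP are bin-level. Only bin-level FN
  reproduces the published ~50% pseudorandom-baseline sensitivity (an
  event-level FN drives a coin-flip baseline to ~100%, because almost
  every Ep contains at least one positive bin), so bins are the scoring
  unit throughout and the event-level miss count is reported separately
  as `missed_events`.
* **Late-grooming bins are excluded.** Bins inside a bout but after its
  Ep end are neither rewarded nor punished; treating them as FP-eligible
  would push the random baseline's specificity visibly below 50%,
  contradicting the published chance level.

Ratios with zero denominators are reported as `NA` with a warning, never
coerced to 0 or 100. Baseline metrics are averaged per session over five
runs, then across sessions.

## 7. Problem sizes and numerical scale

The test suite and the acceptance script run everything at desk scale,
chosen as the package's own validation conditions: synthetic LFP at
250 Hz; eight 10-min training sessions (~290 labeled windows across 32
electrodes); two held-out 10-min assessment sessions; seventeen 2-channel
sessions (>200 events) for ramp recovery; and, for the full OFF/CL/RANDOM
protocol, cohorts of three 36-min sessions per seed across eight seeds —
a runtime-bounded scaling of the published five-animal cohort. All
randomness flows through explicit integer seeds; identical seeds give
bit-identical outputs.

## 8. Known limitations

* **Bin-level sensitivity is structurally capped on the synthetic
  conditions.** The Ep begins 2 s before onset, but the generator's
  biomarker begins 0.9 s before onset and the decision history spans
  1.8 s: bins in [−2 s, −0.9 s] carry no signal any detector could use,
  and bins late in long bouts carry none either once the burst has been
  released. For a mean 4-s bout this bounds bin-level sensitivity near
  65–70% even for an oracle detector, and a calibrated conservative
  detector sits well below that; the high published sensitivity is
  consistent with in-vivo delta power persisting through the Ep and/or
  the event-level FN convention. The acceptance machinery reports the
  honestly computed value; the companion event-level `missed_events`
  count on the same runs is routinely zero (every bout detected).
* **The OFF/CL/RANDOM ordering is noisy at protocol scale.** With the
  simple overlap-based suppression model, randomized (yoked) stimulation
  also cancels bouts whenever it happens to cover a pre-onset window, so
  at realistic stimulation counts the CL-vs-RANDOM margin is a few bouts
  per session against Poisson counting noise; the strict per-seed
  ordering CL < RANDOM < OFF is the expected direction but not a
  near-certain event per cohort. The stimulation-time saving of the
  closed-loop protocol (well under half of the continuous protocol's
  900 s) is robust.
* The classifier bundle stores plain JSON; for 32 electrodes this is a
  few hundred kilobytes and loads in milliseconds, which is adequate
  here, but a binary container would be preferable for much larger
  electrode counts.
* The engine is a faithful simulator of the decision/lockout/stimulation
  logic, not a hard-real-time implementation; latency guarantees and
  hardware I/O are out of scope.
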