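---
title: "Models and methods behind somnarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind somnarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`somnarch` analyzes rodent sleep EEG/EMG the way chronic-recording sleep
labs do — 4-s scoring epochs, FFT band powers, hypnogram architecture,
normalized NREM delta power, deprivation rebound — and ships a generative
model of such recordings so that every analysis stage can be validated
against known ground truth. This vignette documents the models, the
parameters that matter, the numerical conventions, and what the synthetic
data can and cannot establish.

## Timing conventions

Epochs are 4 s, half-open `[i*4, (i+1)*4)` seconds, 0-based. Zeitgeber time
(ZT) is seconds since lights-on; with the default 12:12 schedule an epoch is
in the light phase iff `zt mod 86400 < 43200`. Recordings start at ZT0
(lights-on, 7:00 in wall-clock terms). The deprivation protocol forces
wakefulness during `[ZT0, ZT6)` of the second recorded day — exactly 5,400
epochs — and leaves the following 18 h free.

## The generative model

**State dynamics.** The hypnogram is a first-order Markov chain over
{WAKE, NREM, REM} at the epoch scale, with two row-stochastic 3x3 matrices,
one per lighting phase. A first-order chain is the simplest mechanism that
produces the two features the analyses rely on: geometric-like bout
durations and a light/dark rhythm in state occupancy. It does not produce
ultradian NREM/REM cycling or time-of-day trends within a phase; metrics
sensitive to those (none in this package's battery) would need a richer
model. The chain starts in WAKE at ZT0, reflecting the arousal at lights-on.
REM is entered only from NREM in the shipped presets (the wake-to-REM rate
is zero), though the data model permits and the transition counter reports
all six ordered transitions.

**Line archetypes.** The NAB/LAB/HAB presets encode the *directions* of the
phenotypes of normal-, low- and high-anxiety mouse lines; the magnitudes are
free parameters chosen once, by design against the chain's closed forms (the
stationary occupancy of each matrix and the `1/p` expected bout length),
not fitted to any published group mean:

- `NAB` — consolidated sleep, robust light/dark rhythm (stationary
  light-phase occupancy near 54/42/4% wake/NREM/REM, dark-phase wake near
  80%).
- `LAB` — very slow wake exit in the light phase (per-epoch 0.002 vs NAB's
  0.015), giving long sleep latency and elevated light-phase wakefulness;
  extremely long dark-phase wake bouts (exit 0.005, ~13 min expected);
  a beta-band (19 Hz) component in the NREM signature; and impaired
  slow-wave-pressure accumulation — a long homeostatic rise time constant
  (18 h) toward a low ceiling (1.6) — that blunts its deprivation rebound.
- `HAB` — fast state turnover in every state and phase (fragmentation),
  blunted dark-phase wakefulness, a raised NREM-to-REM entry rate, a larger
  NREM delta signature (5.5 vs 4.0), and a homeostat that never fully
  discharges (floor 1.1 vs 0.6) yet rebounds hard (rise constant 6 h toward
  a 2.6 ceiling): persistently elevated, homeostatically quick delta power.

One subtlety drove the magnitudes: the latency rule requires a
*consolidated* episode, so a fragmented sleeper's latency is set not by its
first sleep epoch but by its first qualifying episode. The wake-exit and
NREM-exit rates were therefore chosen so the expected latency ordering
(LAB far above NAB far above HAB) holds with a wide margin for medians of
ten animals, the scale at which the validation battery evaluates it —
per-animal latencies inherit the geometric skew of the initial wake bout,
so medians of small samples fluctuate strongly.

**EEG synthesis.** Each epoch's EEG is a stationary Gaussian process
synthesized in the frequency domain: target one-sided power per 0.25 Hz bin
equal to `background / max(f, 0.5)` plus Gaussian components
`amp * exp(-(f - center)^2 / (2 bw^2))`. NREM carries a dominant delta
component (center 1.5 Hz) and a small sigma (12 Hz) component; REM a sharp
theta peak (7.0 Hz for NAB, 6.2/6.1 for LAB/HAB, encoding the slower theta
of the extreme lines) over a weaker background; wake a broad low theta over
a stronger background. Complex spectral coefficients with circularly
symmetric Gaussian amplitudes are inverse-FFT'd; the real and imaginary
parts provide the two independent EEG channels (frontal EEG1, parietal
EEG2). Epochs are synthesized independently, so there is no spectral
leakage across epoch boundaries — real recordings have continuous phase and
within-state nonstationarity that this model deliberately omits.

**Homeostatic process.** A two-process-style scalar rises toward a ceiling
(2.2) with time constant `tau_rise_h` during wake and REM and decays toward
a floor (0.6) with `tau_decay_h = 2 h` during NREM, starting at 1.0; it
multiplies the NREM delta component's amplitude. Values are per-epoch at
epoch start, so the process is piecewise-exponential at 4-s resolution and
provably confined to `[floor, ceiling]`. The time constants are in the range
used for rodent slow-wave-activity models (hours-scale rise, faster decay),
but they are free parameters of the simulator, not estimates: no
quantitative homeostatic model is being claimed, only the qualitative
machinery needed for rebound analyses to have something real to detect.

**EMG and artifacts.** The EMG is white noise at a per-state RMS
(wake 3.0 > NREM 1.0 > REM 0.45, arbitrary units) — rectification-free
synthesis, since the analysis side computes RMS per epoch anyway. Artifacts
are injected per epoch with probability `artifact_rate` (default 0.005) as
broadband white transients at `artifact_gain` (10) times the typical epoch
RMS on both EEG channels; the underlying state is retained as ground truth.
Real artifact morphology (movement, chewing, electrode pops) is far more
diverse; the detector below is validated only against this broadband class.

## Spectral analysis

Per-epoch magnitude-squared FFT, one-sided, 256 samples at 64 Hz, hence an
exact 0.25 Hz grid. Power in bin `k` is `2|X_k|^2 / N^2`, so with the
rectangular taper the bin sum equals the epoch mean square (Parseval; tested
to 1e-9 on bin-centered tones). The DC and Nyquist bins are dropped: the
grid runs 0.25–31.75 Hz, and "total power" normalizations cap at the last
full bin below Nyquist (31.75 Hz) since a one-sided 32 Hz bin does not
exist. The default taper is a Hann window renormalized to unit power
(divided by its RMS), which preserves total tone power while suppressing
leakage; the rectangular taper remains available and is what the exactness
tests use. Band edges are inclusive on the grid: delta 0.5–5 Hz spans 19
bins. The delta band is 0.5–5 Hz throughout, with a 0.5–4 Hz preset
(`somn_bands("delta4")`) for the narrower convention some delta time-course
displays use.

Two normalizations coexist deliberately:

- the **NREM delta time course** divides each bin's mean NREM delta power by
  the animal's 24-h baseline mean of total 0.5–29 Hz power over NREM epochs
  (a per-animal scalar; recovery days reuse the baseline scalar so the two
  days share a scale), and
- **state profiles / band tables** divide by the mean total power over the
  full grid across *all* unmasked epochs of the day. The pooled (all-state)
  denominator is used rather than a per-state one; the package's own
  algebraic identity — profile sum = 100 x state mean total / grand mean
  total — is tested to 1e-10.

Empty bins and empty state-interval cells are `NA`, never zero, and
propagate as `NA` through group summaries.

**Artifact flagging** marks an epoch when its total 0.5–29 Hz power exceeds
`k = 8` times a centered rolling median (window ±450 epochs, i.e. ±30 min).
The rolling window tracks the slow homeostatic drift in total power; `k` is
far above the ~40% coefficient of variation of clean epoch power, which is
why the false-positive rate stays below 1% while the injected 100x-power
transients are caught essentially always. Upstream hypnogram flags are
OR-ed in, and masked epochs carry zero weight in every average.

## Scoring

The classifier is an explicit decision rule, not a reimplementation of any
lab's proprietary scorer: the validation target is recovery of known
synthetic labels, not equivalence to a particular program. Per epoch, with
precedence WAKE, REM, NREM:

1. WAKE if EMG RMS ≥ `emg_wake_cut`;
2. else REM if EMG RMS ≤ `emg_atonia_cut` and theta/total ≥
   `theta_ratio_cut`;
3. else NREM if delta/theta ≥ `delta_ratio_cut`;
4. else the nearest class, measured as the sum of the rule's normalized
   shortfalls (distance to each unmet cut divided by the feature's MAD, EMG
   and delta/theta on the log scale), ties resolving in precedence order.

Quantile calibration is per-recording and parameter-light: the EMG wake cut
is the density antimode of log EMG RMS between its two main modes (muscle
tone is bimodal across wake and sleep), with the 60th percentile as the
fallback when no valley exists — a pure quantile cut mislocates whenever
wake occupancy strays far from the quantile, exactly what a wake-dominated
phenotype does; the atonia cut is the 20th percentile; ratio cuts are
density antimodes computed among sub-wake epochs (where the NREM/REM
contrast is bimodal), falling back to fixed quantiles when no valley
exists. Because every cut is
a quantile or antimode of the recording's own features, positive rescaling
of EEG or EMG leaves the labels bit-identical (tested). Calibration refuses
recordings under 100 epochs or with degenerate features. The labeled
variant grid-searches cuts against a reference hypnogram and keeps whichever
of (grid cuts, quantile cuts) scores the labeled epochs better, so it can
never be the worse of the two on its training labels.

Smoothing is a single left-to-right pass relabeling isolated single-epoch
states whose two neighbors agree — a minimal automated stand-in for visual
confirmation — and can be disabled. Manual corrections are pointwise, with
an audit log kept as an attribute.

On synthetic studies the self-calibrated classifier recovers ~99.7% of
epochs (kappa ≥ 0.99, REM recall ≥ 0.99) in all three archetypes. That
figure validates the pipeline's internal consistency, not performance on
real mice: the synthetic features are cleanly separated by construction,
with no transitional epochs, drowsy wake, or electrode drift.

## Architecture metrics

Bouts are maximal same-state runs; restricted to an interval, runs are
clipped at the boundary, so a run spanning lights-off contributes one bout
to each side. Transitions count adjacent differing-state pairs, with a pair
straddling the boundary credited to the interval containing the later
epoch. These two conventions are arbitrary but fixed, and they interlock:
every bout receives exactly one incoming credited transition unless it
opens the recording or continues a same-state run across the boundary — an
identity the test suite checks on every random input alongside the
conservation laws (bout lengths tile the interval; state percentages plus
the artifact-excluded fraction sum to 100).

Sleep latency scans forward from a reference (lights-on, or deprivation end
ZT6) for the earliest window that starts and ends in the target state,
spans ≥ 15 epochs, and contains ≤ 6 non-target epochs *in total* — the
span reading of "an episode lasting at least 15 epochs with an allowance of
6 interrupted epochs", with the interruption allowance counted per episode.
The alternative net reading (≥ 15 target epochs net of interruptions) is
available via `rule = "net"`. Latency is antitone in the allowance and
isotone in the span requirement (property-tested). Artifact epochs count as
their best-guess state in all architecture metrics (they were excluded only
from spectral averages), with `NA`-state epochs breaking runs and counting
as non-target; an analysis that wants them excluded can drop them upstream.

## Deprivation rebound and statistics

Rebound tables subtract baseline from recovery per matched ZT bin (2-h or
6-h), per measure (NREM%, REM%, normalized delta). Bins fully inside the
deprivation window are reported but flagged, for wake-enforcement QC only.
Differences are `NA` unless both days have a defined value; nothing is
imputed. The group-statistics surface — one-way and two-way fixed-effects
ANOVA, Bonferroni-adjusted pairwise Welch t-tests, Tukey HSD, paired
t-tests — delegates to base R's well-tested routines (`aov`,
`pairwise.t.test` with `pool.sd = FALSE`, `TukeyHSD`, `t.test`); the
package's contribution there is the tidy surface and degenerate-input
handling (zero-variance data yields a "non-testable" report, not an error).
Whether the original analyses treated interval as a repeated measure within
animal is unknowable from the outside; the fixed-effects treatment is used,
and dispersion is reported as SEM where reported at all.

## Problem sizes and determinism

Every stochastic element flows through R's RNG: a study seed expands into
per-animal seeds, each animal's signal synthesis derives its seed from its
chain seed (+1, so signal draws never replay chain draws), and identical
seeds reproduce hypnograms, signals and downstream tables bit for bit. The
shipped validation battery uses 10 animals per line (48-h sessions, full
signal synthesis) for the phenotype and rebound checks, 10,000 random
21,600-epoch hypnograms for the oracle-equivalence checks, 2x10^5 epochs
for the transition-frequency calibration (total-variation distance < 0.02
per row), and 1,000 replicate null studies (three relabeled groups of four
12-h animals) for the ANOVA type-I calibration — sizes at which the
measured quantities' Monte-Carlo error is several times smaller than the
margins being asserted.

## Known limitations

- The Markov chain has no ultradian NREM/REM cycle structure and no
  within-phase circadian modulation; bout-duration tails are geometric,
  while real bouts are often heavier-tailed.
- The archetypes encode a specific subset of phenotype directions (latency,
  fragmentation, bout durations, delta level, rebound, theta peak); other
  published contrasts are not all preserved — in particular the HAB preset's
  light/dark amplitude of wake occupancy comes out *larger* in magnitude
  than NAB's, not attenuated, and post-deprivation latencies are not
  shortened relative to baseline because homeostatic pressure does not feed
  back onto the transition rates.
- Epoch-independent synthesis means no spectral continuity across epochs
  and no transitional (state-mixture) epochs — the classifier's near-perfect
  recovery is an upper bound, not a field estimate.
- The homeostatic process is a two-parameter saturating exponential; it is
  qualitatively, not quantitatively, matched to slow-wave-activity
  dynamics.
- The EDF reader targets the 16-bit single-rate files the package writes;
  exotic EDF+ features (annotations, discontinuous records) are out of
  scope, and physical-dimension oddities are warnings rather than errors.
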