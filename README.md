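# somnarch

Sleep-wake architecture and EEG spectral analysis for rodent polysomnography,
with a fully seeded synthetic data generator for validating every stage of
the pipeline against known ground truth.

## The problem

Rodent sleep studies score chronic EEG/EMG recordings into vigilance states
— wakefulness, NREM sleep and REM sleep — in 4-s epochs, and then reduce the
resulting hypnogram and spectra to a standard battery of phenotyping
measures: time in state per light/dark interval, bout numbers and durations,
state-transition (fragmentation) counts, latency to consolidated sleep, EEG
band powers per state, the normalized NREM delta-power time course that
indexes homeostatic sleep pressure, and the delta-power rebound after
enforced sleep deprivation. `somnarch` implements that battery end to end
for 64 Hz EEG/EMG recordings on a 12:12 light/dark schedule:

- **Spectra** — per-epoch FFT power on an exact 0.25 Hz grid (256 samples at
  64 Hz), rolling-median artifact rejection, band powers (delta 0.5–5,
  theta 6–9, sigma 10–15, beta 16–23 Hz), two normalization conventions
  (NREM delta relative to the 24-h NREM 0.5–29 Hz mean; state profiles and
  band powers relative to 24-h total power), and REM theta-peak frequency.
- **Scoring** — a transparent, self-calibrating decision rule per epoch:
  wake when EMG RMS is high; REM when the EMG shows atonia and the EEG is
  theta-dominant; NREM when delta dominates theta; nearest-cut fallback,
  single-pass smoothing, manual-correction hooks with an audit log.
- **Architecture** — bouts (maximal runs), the six ordered state
  transitions, state amounts in 2-h/12-h bins, light-minus-dark amplitudes,
  and the consolidated-sleep latency rule (an episode spanning ≥ 15 epochs
  with ≤ 6 interrupted epochs).
- **Homeostasis** — recovery-minus-baseline rebound tables in 2-h/6-h ZT
  bins, post-deprivation latencies, and the usual group statistics (one- and
  two-way ANOVA, Bonferroni, Tukey HSD, paired t-tests).
- **Synthetic data** — an inhomogeneous Markov chain over states with
  phase-dependent per-epoch transition matrices; state-specific EEG spectral
  signatures over a 1/f background; a two-process-style homeostatic process
  (exponential rise toward a ceiling during wake/REM, decay toward a floor
  during NREM) that scales the NREM delta amplitude; EMG tone by state;
  artifact transients; a 6-h forced-wake protocol at light onset; and three
  line archetypes (NAB/LAB/HAB) encoding high-, normal- and low-anxiety
  sleep phenotypes. EDF and CSV input/output round-trip the recordings.

## Worked example

```r
library(somnarch)

cfg <- archetype_config("NAB", n_hours = 2, seed = 11)
hyp <- simulate_hypnogram(cfg)          # ground-truth states
rec <- simulate_signals(hyp, cfg)       # EEG1/EEG2/EMG at 64 Hz

sp <- compute_epoch_spectra(rec)        # 1800 epochs x 127 bins
sp$artifact_mask <- flag_artifacts(sp)
feats  <- extract_features(sp, rec)
th     <- calibrate_thresholds(feats)   # self-calibrating cuts
scored <- smooth_hypnogram(classify(feats, th))
score_agreement(scored, hyp)[c("accuracy", "kappa")]
#> $accuracy
#> [1] 0.9994417
#> $kappa
#> [1] 0.9989149

architecture_summary(hyp)$latency
#> # A tibble: 2 x 2
#>   target latency_min
#>   <chr>        <dbl>
#> 1 NREM          8.13
#> 2 REM          26
```

The self-calibrated classifier recovers 99.9% of the ground-truth epochs
(kappa 0.999; full 24-h studies across all three archetypes land around
99.6% with kappa ≥ 0.99), and the latency rule dates the first consolidated
NREM episode at 8.13 min after lights-on.

The numbered scripts under `analysis/` run the full study workflow over the
shipped line archetypes — simulate (`01`), score (`02`), architecture
(`03`), spectra (`04`), deprivation rebound (`05`) — and write tidy CSV
tables under `results/`.

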