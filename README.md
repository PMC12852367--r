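# sleeposc

Analysis pipeline for nap-sleep EEG recorded around blocked
slow-oscillatory transcranial current stimulation (so-tDCS), plus a
synthetic polysomnography generator that provides ground truth for every
stage.

During NREM sleep, cortical slow oscillations (SO, < 1 Hz) coordinate
thalamocortical sleep spindles (12–15 Hz): spindles preferentially occur
near the SO up-state, and the precision of this phase coupling supports
memory consolidation. Weak sinusoidal currents delivered in one-minute
blocks during a nap are thought to modulate these rhythms; because the
stimulation itself saturates the EEG, all analysis operates on the
one-minute artifact-free windows that follow each stimulation (or sham)
block. This package implements that analysis chain for a three-condition
within-subject design (sham, anodal, cathodal):

- **SO event detection** — FIR band-pass 0.16–1.25 Hz, cycles delimited by
  consecutive positive-to-negative zero-crossings with durations in
  0.8–2 s, retained when their trough-to-peak amplitude reaches the
  session's individualized 65th percentile (age-appropriate, no fixed
  µV threshold). Event morphology: down-state magnitude, up-state
  amplitude, peak-to-peak amplitude, trough-to-peak slope, and
  negative/positive half-wave durations.
- **SO-locked time–frequency maps** — complex Morlet (5 cycles), 10–20 Hz
  in 0.2 Hz steps at 50 Hz, z-scored against the −2.35 to −1.5 s
  pre-trough baseline, compared between conditions with paired t maps and
  threshold-free cluster enhancement (TFCE, E = 0.5, H = 2) under a
  sign-flip permutation test.
- **Event-locked SO–spindle coupling** — per SO event, the SO phase (0° =
  up-state peak, 180° = trough) at the time of maximal spindle-band
  (12–15 Hz) envelope within ±2 s of the trough; summarized per subject ×
  condition as the circular mean angle and the resultant vector length R,
  compared across conditions with Watson–Williams tests.
- **Aperiodic spectral slope (E/I proxy)** — log–log linear fit of the
  Welch PSD over 1–45 Hz (fixed form, single-pass peak exclusion); the
  slope −x flattens when excitation rises relative to inhibition.
- **Group statistics** — repeated-measures ANOVA with Greenhouse–Geisser
  correction, Holm–Bonferroni planned contrasts with paired Cohen's d,
  repeated-measures ANCOVA with the continuous MEQ chronotype score as
  moderator (Condition × MEQ), a mixed Condition × Chronotype ANOVA
  (morning ≥ 59 vs intermediate/evening 42–58), and Pearson/OLS
  regressions.
- **Synthetic generator** — 1/f^x aperiodic background (x recoverable to
  ±0.1), isolated K-complex-like SO cycles with known trough times and
  amplitudes, spindle bursts planted at von Mises-distributed SO phases,
  a blocked stimulation protocol with annotations, and cohorts with
  plantable condition effects and MEQ-moderated effects.

## Worked example

```r
library(sleeposc)

# one synthetic stimulation session with ground truth
cfg <- synth_config(duration = 1200, noise_seed = 20260925)
gen <- generate_recording(cfg, stim_protocol(n_blocks = 7))

# detect slow oscillations in the post-block windows
det <- detect_so_in_recording(gen$recording)
summarize_morphology(det$events)
#>   count downstate_mag upstate_amp p2p_amp slope neg_halfwave_dur pos_halfwave_dur
#> 1    75         38.26       37.81   76.07 128.4           0.6691           0.6757

# event-locked SO-spindle coupling
blocks <- subset(gen$recording$annotations, label == "STIM_BLOCK")
eps <- extract_event_epochs(select_channel(gen$recording)$signal,
                            det$events, gen$recording$fs,
                            avoid = cbind(blocks$onset,
                                          blocks$onset + blocks$duration))
circular_summary(event_locked_pac(eps, gen$recording$fs))
#> $mean_angle  336.2   # generator plants vonMises(333 deg, kappa = 4)
#> $R           0.513
#> $n_events    71
```

The mean angle is the preferred SO phase of spindle maxima (336° ≈ late
rising phase, just before the up-state peak — the physiological
coupling); R is the coupling strength (0 = uniform, 1 = perfectly
phase-locked).

A full cohort analysis, from simulation through the group statistics
report, is in `analysis/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_run_pipeline.R
Rscript analysis/03_group_stats.R
```

On the default planted effects (12 subjects) the final report shows the
planted pattern: spindle power raised after anodal stimulation (paired
d ≈ 1.1, Holm-adjusted p ≈ 0.005), the preferred coupling phase shifted
by ≈ +14° toward the up-state (Watson–Williams p ≈ 0.01), a strong
negative MEQ moderation of the anodal spindle gain (r ≈ −0.94), a
flattened spectral slope after anodal stimulation, and no cathodal
effects.

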