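---
title: "Methods: slow-oscillation, coupling and spectral-slope analysis of stimulated nap EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slow-oscillation, coupling and spectral-slope analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its methods: the signal models,
the estimators, the numerical choices, and what the synthetic-data tests
do and do not establish about real recordings.

## The analysis problem

Slow-oscillatory transcranial current stimulation is delivered in
one-minute blocks during N2/N3 nap sleep, separated by stimulation-free
gaps of at least 1.5 minutes. The stimulation saturates the EEG, so the
scientific signal lives in the one-minute windows that follow each block.
Within those windows the pipeline quantifies, per subject and condition
(sham, anodal, cathodal): spectral band power, slow-oscillation (SO)
event morphology, SO-locked spindle-band time–frequency structure,
event-locked SO–spindle phase coupling, and the aperiodic spectral slope
as an excitation/inhibition (E/I) proxy; a group layer then runs the
within-subject statistics with chronotype moderation.

## Preprocessing

Recordings travel as multi-channel matrices in microvolts with an
annotation track (`STIM_BLOCK`, `POST_WINDOW`, `STAGE_*`). EDF I/O is a
minimal 16-bit implementation with a CSV sidecar for annotations; the
physical range is set per channel, so the quantization step is
`2*max|x|/65534` µV. The notch is a cascade of second-order IIR notches
(Q = 30) at the base frequency and harmonics, applied forward–backward so
the net filter is zero-phase. Resampling combines a zero-phase
windowed-sinc low-pass at 0.45 × the target rate with cubic-spline
regridding; we implemented it directly after measuring > 1% passband
amplitude error in the available polyphase routines, which would have
violated the resampling contract (tone amplitude within 1%). The analysis
channel is the first usable fronto-central derivation (Fz, then FC1,
FC2).

Post-block analysis intervals are 60 s from each block offset, clipped at
the next block onset; clipped windows are excluded by default so every
PSD rests on the same window length. One 60-s pre-stimulation baseline
ends at the first block onset.

## Spectral estimation

Welch's method on 4-s segments, 50% overlap, Hamming window, per-segment
constant detrend: a 0.25 Hz grid. Density normalization is one-sided
(integrating the PSD of white noise recovers its variance; enforced by a
Parseval test). Band power is a trapezoidal integral; relative power
divides by the 0.5–35 Hz total, with zero total power mapping to relative
power 0 plus a warning so degenerate synthetic inputs cannot poison
tables. One PSD per 60-s window (not a median of sub-spectra), which is
what "consecutive 4-s epochs with 50% overlap" describes.

## SO event detection

The signal is band-passed at 0.16–1.25 Hz with a windowed-sinc FIR
(Hamming; transition 0.1 Hz at the low edge, 0.5 Hz at the high edge),
applied with exact delay compensation (zero phase). Candidate cycles are
delimited by consecutive positive-to-negative zero-crossings 0.8–2 s
apart — a negative half-wave followed by a positive one. The trough is
the cycle's most negative sample; the separating up-crossing is the first
crossing *after* the trough (anchoring on the first interior crossing
breaks when small wiggles ride the half-wave tails). Events are the
candidates whose trough-to-peak amplitude reaches the session's 65th
percentile (type-7 interpolation, comparison `>=` so an all-ties session
keeps its events). The threshold is deliberately session-internal — an
individualized, age-appropriate criterion rather than a fixed microvolt
cut — and therefore *not* additive across sessions; a test pins this
down. Slope is trough-to-peak amplitude over trough-to-peak time.

A consequence worth stating explicitly: a percentile rule retains exactly
the top 35% of candidate cycles, whatever the signal. Recovery of planted
events in synthetic data is then governed by an identity — recall can be
at most `0.35/f` and precision at most `f/0.35`, where `f` is the planted
fraction of candidate cycles. Both exceed 0.9 only when `f ≈ 0.32–0.39`.
The generator's default event rate is chosen to sit in that regime (see
below), which is also the regime the individualized threshold implicitly
assumes in real data: the events of interest are the top third of
SO-band cycles.

## SO-locked time–frequency maps and TFCE

Five-second trough-centered epochs are downsampled to 50 Hz, transformed
with complex Morlet wavelets (5 cycles, unit-energy) on a 10–20 Hz grid
in 0.2 Hz steps, and trimmed by 150 ms per edge. Each epoch is z-scored
per frequency against the −2.35 to −1.5 s baseline; an epoch with zero
baseline variance at any frequency is flagged and excluded rather than
propagating NaN. Subject-level input to the group test is the mean
z-scored map over that subject's SO epochs.

Condition differences use pixelwise paired t maps and threshold-free
cluster enhancement with the canonical exponents E = 0.5, H = 2,
integrated in 100 steps of height `dh = max|t|/100`; adjacency is
4-connected on the time × frequency grid (conservative, grid-native).
Inference is a sign-flip permutation test on the per-subject difference
maps — valid for a paired design — with the familywise null being the
maximum |TFCE| per permutation and corrected p-values
`(1 + #{null ≥ obs})/(n_perm + 1)`. When `2^n ≤ n_perm` all sign patterns
are enumerated and the p-values are exact. The TFCE transform itself is
compiled (union-find over sorted pixels) so that the 200-replicate null
calibration runs in seconds; a zero-variance pixel maps to a large finite
t (sign preserved) rather than infinity. Calibration on pure-noise
cohorts puts the familywise false-positive rate at the nominal 5% (test
band 2–10%).

## Event-locked SO–spindle coupling

Within each trough-centered epoch, restricted to ±2 s to avoid filter
edges: the SO phase series comes from a complex-Morlet transform of the
0.5–1.25 Hz band (center 0.875 Hz, spectral SD a quarter of the
bandwidth). We use the wavelet rather than a sharp FIR plus analytic
signal because an FIR with a sub-hertz transition is an order of
magnitude longer than the 5-s epoch and measurably biases phase; for an
in-band tone the wavelet argument *is* the instantaneous phase. The
convention — 0° at the SO positive peak, 90° mid-falling, 180° at the
trough, 270° mid-rising — is enforced by calibration tests on a known
cosine, because sign and rotation conventions differ silently between
implementations. The spindle envelope is the magnitude of the analytic
representation of the 12–15 Hz band. Per event, the SO phase at the time
of the maximal spindle envelope (earliest sample on ties) yields one
spindle-at-peak phase; per subject × condition these summarize into the
circular mean angle and resultant vector length R. Events are pooled
within subject first; subject-level means feed the group comparisons.

Group comparison of mean directions uses the Watson–Williams F with the
`1 + 3/(8κ)` concentration correction, κ estimated from the pooled mean
resultant length; a low-concentration flag warns when the approximation
weakens (mean resultant length below ~0.45). The von Mises sampler is
Best–Fisher rejection. Both are implemented here because no circular
statistics package is available in the target environment; type-I
calibration sits at 5.0% over 500 replicates.

## Aperiodic slope

`log10 PSD = offset − x·log10 f` over 1–45 Hz, no knee ("fixed" form).
Oscillatory peaks are handled by a single-pass robust refit: points more
than 2.5 residual SD above the first fit are excluded once. This is a
deliberate simplification of full peak-Gaussian decomposition; the
normative contract — the exponent is unbiased (±0.1) in the presence of a
narrow spindle-band peak — is what the tests enforce, and a full
peak-model backend could be swapped in behind the same signature. Tables
report the slope (−x) so "less negative = more excitable" reads
naturally.

## Group statistics

One-way repeated-measures ANOVA in closed form (condition, subject and
error sums of squares), with the Greenhouse–Geisser ε from the
double-centered condition covariance applied unconditionally (the
uncorrected p is reported alongside; no sphericity gate). The
implementation is cross-checked in the test suite against an independent
multivariate-model route to four decimals. Planned contrasts
(cathodal–sham, anodal–sham) are paired two-tailed t-tests under Holm
step-down adjustment with paired Cohen's d (`mean(diff)/sd(diff)`);
contrasts are always computed and carry a flag recording whether the
omnibus passed, so exploratory reuse has the numbers. The
condition × MEQ moderation enters centered MEQ into the within-subject
stratum (subject effect absorbed), giving the interaction F on
((k−1), (k−1)(n−2)) degrees of freedom with ε estimated from
covariate-adjusted per-condition residuals. The mixed
condition × chronotype ANOVA uses a multivariate linear model with type
III sums of squares (groups of 12 and 10 are unbalanced by design) and
reports per-group paired contrasts. MEQ classification: ≥ 59 morning,
42–58 intermediate/evening; scores below 42 fold into the second group
with a flag, closing the dichotomy.

## The synthetic generator as study conditions

The generator is the package's ground truth and encodes explicit, frozen
choices. Where the protocol literature fixes a value we use it
(0.75 Hz, 5–255 µA, 8-mm electrodes — giving the 0.507 mA/cm² peak
current density — 1-min blocks, ≥ 1.5-min gaps, 7–15 blocks). The rest
are the generator's own study conditions, set once:

- **Aperiodic background**: spectrally shaped Gaussian noise with
  one-sided PSD `10^offset · f^{−x}` above a 0.4 Hz plateau, exactly
  log-log linear over the 1–45 Hz fit range. The plateau is the
  low-frequency knee seen in neural spectra; it also matters mechanically,
  because unbounded sub-SO drift displaces the zero-crossings that define
  detection cycles. Default x = 2, offset 1 (10 µV²/Hz at 1 Hz).
- **SO events**: one full cycle `−A·sin(2πt/T)` (negative half first),
  flanked by a +20–30% lead-in bump and a −20–30% rebound (0.35 s
  half-sines) — the K-complex-like morphology of real slow oscillations.
  The flanks are not cosmetic: a template that merely touches zero at its
  endpoints leaves the cycle-delimiting crossings to the whim of the
  background, and planted durations then leak out of the 0.8–2 s window
  even at high SNR. T is drawn from 0.6–0.95 Hz (1.05–1.67 s), clear of
  the duration-window edges because band-limiting broadens cycles by
  5–8%. Amplitude A ~ N(40, 8) µV floored at 20 µV, i.e. every planted
  event honors the detectability premise of the recovery contract.
  Default rate 18/min with ≥ 1.2 s silence between cycles, putting
  planted events at ~35% of candidate cycles (see the percentile identity
  above).
- **Spindles**: Gaussian-envelope bursts (SD = duration/6, default
  0.75 s) at 13 Hz, amplitude 15 µV, planted with probability 0.5 per SO
  at an SO phase drawn from vonMises(333°, κ = 4) — late rising phase,
  the physiological preference; κ = 4 corresponds to a circular SD near
  30°, matching the dispersion reported for aged sleepers.
- **Cohort**: MEQ ~ round N(60, 7) clipped to 16–86, skewed toward
  morningness as in aged samples. Planted effects shift, per condition,
  the coupling phase, the aperiodic exponent, and spindle amplitude, the
  last optionally with a linear MEQ slope (centered at 60) — the
  moderation structure. Per-cell seeds derive deterministically from the
  master seed.

What passing recovery tests establish: the estimators are unbiased and
appropriately calibrated *under this generative model* — isolated events
on a stationary 1/f background, stationary coupling, no arousals, no
artifacts beyond the stimulation blocks, no REM, no topography (three
statistically identical frontal channels). Real EEG violates all of
these; in particular, real SO-band activity is a continuous oscillation
whose "events" are simply its largest cycles, so planted-truth recall and
precision have no direct analogue there. The tests validate the
machinery, not the biology.

## Problem sizes and reproducibility

The shipped analyses use scaled-down but fully structured designs: 12
subjects × 3 conditions × ~18-minute sessions for the `analysis/`
workflow, 22 subjects × 2 conditions for the coupling-shift recovery,
200 null replicates at 256 permutations for the TFCE calibration and 500
replicates for the analytic calibrations, chosen to exercise every code
path at meaningful power. Everything is deterministic given (config,
seed): generation consumes named sub-seeds, permutation seeds are logged
in the result, and two pipeline runs with the same configuration produce
byte-identical tables — a test asserts exactly that.

A note on interfaces: the pipeline is exposed as R functions plus the
numbered scripts under `analysis/`; `run_pipeline()` is the single
entry point that sequences every stage, so no separate shell wrapper is
shipped.

## Known limitations

- The EDF layer targets the files this package writes (uniform rate,
  µV); it is not a general EDF+ reader.
- The Watson–Williams test assumes reasonably concentrated von Mises
  samples; it warns rather than switching to a nonparametric alternative.
- The peak-exclusion slope fit handles narrow peaks; broad or multiple
  overlapping peaks would call for a full peak-decomposition backend.
- Coupling strength R at the subject level conflates event count with
  concentration for very small event counts; sessions with few events
  should be interpreted with care.
- Stage labels are consumed, never inferred: the generator writes minimal
  N2/wake annotations and automated sleep staging is out of scope.
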