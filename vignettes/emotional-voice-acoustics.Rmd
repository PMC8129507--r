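---
title: "Methods: synthesis, feature extraction and mixed-design analysis of emotional voice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthesis, feature extraction and mixed-design analysis of emotional voice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emovoice)
```

## The problem

Emotional state changes the voice along four physical dimensions — time,
frequency, amplitude and spectrum — and these changes are measurable as
seven acoustic features: speech velocity (seconds per word), mean
fundamental frequency F0, F0 variability (F0 SD), intensity (dB), jitter
(%), shimmer (%) and the harmonics-to-noise ratio HNR (dB). Studies of
gender-by-emotion voice production summarize such features in a two-way
mixed design: gender is a between-subjects factor, the emotional state a
nine-level within-subjects factor — a neutral benchmark plus the eight
sign octants of the pleasure–arousal–dominance (PAD) emotion cube
(`pad_emotions()`, `octant_to_emotion()`).

`emovoice` implements this workflow end to end, and — because raw study
audio of this kind is rarely deposited — pairs it with a seeded
synthetic-voice generator whose control parameters are *exactly* the
seven features the extractor estimates. Parameter recovery on synthetic
audio is therefore the package's primary validation surface: every
estimator is checked against stimuli whose ground truth is known by
construction.

## The synthetic voice model

An utterance is a sequence of voiced word segments separated by silent
gaps. Each voiced segment is a glottal pulse train:

* **Pitch periods.** Cycle durations are
  $T_i = (1 + \varepsilon_i)/f_{0,i}$, where $\varepsilon_i \sim
  N(0, \sigma_j)$ is the cycle-to-cycle jitter perturbation and
  $f_{0,i}$ a slow F0 contour. The calibration
  $\sigma_j = (\text{jitter}/100)\cdot\sqrt{\pi}/2$ follows from
  $E|X - Y| = 2\sigma/\sqrt{\pi}$ for iid normals, so the expected
  consecutive-difference statistic equals the jitter target; the same
  construction calibrates per-cycle amplitudes $A_k = 1 + \eta_k$ to the
  shimmer target. Both are verified by brute-force simulation in the
  test suite (50 seeds at 5000 periods agree with targets of 1, 2 and
  5 % to within 2 % relative).
* **F0 contour.** The contour is a sum of eight random sinusoids drawn
  from the 0.5–3 Hz band with total variance $f_{0,SD}^2$. A reflected
  random walk was considered and rejected: its stationary distribution
  is uniform with SD $\sqrt{3}$ times the nominal step bound, so the
  generator could not hit its own F0-SD target. The sinusoid sum has the
  stated SD exactly, is smooth (keeping contour variation separable from
  jitter), and stays bounded within $[0.6, 5/3]\times$ mean F0.
* **Pulse shape.** Each cycle contributes one band-limited pulse
  centered exactly at its onset instant: one nominal cycle of the first
  $H$ harmonics of mean F0 with $1/h$ roll-off, Hann-tapered to zero at
  $\pm 0.6$ nominal cycles. Centering the pulse on the onset makes the
  rendered peak spacing equal the period sequence cycle-for-cycle —
  with peaks at mid-cycle instead, peak spacing averages adjacent
  periods and the measurable jitter is halved. $H$ is capped at
  min(8 kHz, 0.45 · sample rate): keeping the glottal peak a few samples
  wide lets sub-sample peak interpolation work accurately, while the
  spectrum stays harmonically rich.
* **Noise and level.** White Gaussian noise is added at power
  $P_h / 10^{\mathrm{HNR}/10}$, and the waveform is scaled so the
  extractor's intensity convention (20·log10(RMS/2·10⁻⁵), samples
  treated as pressure-equivalent) returns the intensity target; 70 dB,
  the fixed recording input level of the emulated protocol, is the
  default. The absolute dB anchor is arbitrary — without calibrated
  hardware only the shared convention matters — but because generator
  and extractor share it, intensities round-trip. A sample that would
  exceed full scale is an error, never a silent clamp.

### The preset cohort

`emotion_presets()` carries one parameter vector per (gender, emotional
state) cell, populated from the printed per-cell means of the emulated
study: seconds per word, mean F0, F0 SD, intensity, jitter, shimmer and
HNR for all 18 cells. Cells without a printed mean (F0 SD outside the
four states with reported contrasts; jitter for disdainful and hostile;
HNR for disdainful and anxious) fall back to the per-gender pooled mean
of that feature's printed cells; unprinted intensity cells fall back to
the 70 dB input level. `generate_cohort()` emulates the study design —
31 + 31 subjects by default, each producing all nine states — giving
every subject a persistent relative offset per parameter
(`between_subject_sd`, default 10 %, a typical between-speaker spread
for voice parameters). Intensity's offset is relative on *amplitude* —
an additive dB shift of `20·log10(1+δ)` — since scaling the dB number
itself would mean order-of-magnitude amplitude swings. With zero scatter
the ground-truth cell means reproduce the presets exactly.

What the generator does *not* emulate: phonemes, formants, lexical
content, breath groups, microprosody, or any dependence between the
seven parameters beyond what the presets encode. Passing recovery tests
show the estimators are correct for signals obeying the stated source
model; they do not certify accuracy on conversational speech.

## Feature extraction

`detect_pitch_periods()` works in two stages.

1. **Frame analysis.** 60 ms frames every 10 ms; per frame the
   normalized autocorrelation (FFT-based, normalized by the energies of
   the two lag-shifted segments) is searched over the 75–600 Hz lag
   band. The highest interior local maximum is refined by parabolic
   interpolation; among peaks within 15 % of the best one the smallest
   lag wins, which guards against octave errors when twice the true
   period also lies in the band. Frames whose peak falls below the
   voicing threshold (0.45) or whose energy sits 25 dB below the peak
   frame are unvoiced.
2. **Cycle marking.** Within each voiced run, the strongest waveform
   peak anchors a walk that locates one glottal peak per predicted cycle
   (search window 0.7–1.3 local periods, local period interpolated from
   the frame track). Peak position *and* amplitude are refined with
   3-point parabolic interpolation: at 44.1 kHz a glottal peak is only a
   few samples wide, and without sub-sample refinement the sampling grid
   alone injects spurious jitter and shimmer of several tenths of a
   percent.

The period-based statistics follow the two-point perturbation formulas:
jitter% is the mean absolute consecutive period difference over the mean
period; shimmer% the analogue on per-cycle peak amplitudes; mean F0 and
F0 SD are computed over per-cycle instantaneous F0 (`1000/T_i`), not
over the frame track, matching the period formalism. Adjacent pairs that
straddle a voicing gap are never differenced. Sequences with fewer than
two periods yield `NA` markers, never fabricated zeros.

Frame HNR is $10\log_{10}(r'/(1-r'))$ at the detected period lag, capped
at 60 dB, and the utterance HNR is the mean of frame HNRs *in the dB
domain* — an explicit choice; power-domain averaging would weight clean
frames more heavily. Intensity is the energy mean over voiced frames;
both HNR and intensity exclude frames whose analysis window straddles
silence, since such edge frames mix speech and pause energy.

Velocity divides speech time by the word count. With a word-boundary
annotation the speech time is the summed word spans; without one, 5 ms
energy windows segment the recording and silent runs of at least
`min_pause` (0.10 s) are excluded. The frame-free segmentation is
deliberately coarse — word boundaries are the reliable path, and the
synthetic cohort always carries them.

### Identifiability limits

Two confounds are inherent to the autocorrelation method, not quirks of
this implementation:

* **Jitter caps measurable HNR.** Cycle-length perturbation decorrelates
  the signal at the period lag, so with ≥ 1 % jitter the measured HNR
  saturates far below a high injected target. HNR recovery is therefore
  validated on noise-injection stimuli with zero jitter and shimmer, the
  regime in which the quantity is identifiable.
* **Fast F0 contours leak into jitter.** The per-period step of a large
  F0 SD contour adds to the consecutive-difference statistic. Jitter
  recovery tests use a small contour SD (2 Hz); conversely, jitter
  contributes `f0 · σ_j` of apparent F0 SD, negligible against the
  preset F0 SD values.
* The parabolic lag interpolation gives the HNR estimator a measurement
  ceiling near 37 dB; all voiced HNR values of interest (5–25 dB) sit
  well below it, and the analytic mapping `harmonicity_db()` is exact.

## The mixed-design analysis

`mixed_anova()` fits the classical split-plot decomposition by cell-mean
algebra: gender is tested against subjects-within-gender; state and
gender×state against the state-by-subjects-within-gender stratum.
Balanced groups use the exact classical sums of squares (verified
against a brute-force oracle and against `aov()` with an
`Error(subject/state)` stratum to 10⁻⁶ relative); unbalanced groups fall
back to unweighted cell means with the harmonic mean group size.
Subjects missing any state are dropped listwise with a warning, the
classical repeated-measures requirement.

Sphericity is handled with the Greenhouse–Geisser epsilon — the
conservative standard, computed from the eigenvalues of the
double-centered pooled within-group covariance and clamped to
$[1/(k-1), 1]$ — applied to the within-stratum degrees of freedom, which
is what produces fractional dfs in report tables. Under a deliberately
non-spherical null (heterogeneous variances, AR(1)-like correlation) the
corrected state test's type-I error stays within [0.03, 0.07] at
α = 0.05 over 1000 replicates.

Effect sizes are partial ω², `(SS - df·MS_err)/(SS + (N - df)·MS_err)`
floored at zero, with each effect's own error stratum; several ω²
variants reproduce plausible values for published tables, so the variant
is documented rather than inferred. Simple main effects follow reporting
practice: a one-way repeated-measures ANOVA per gender (own GG
correction) and a two-sample comparison per state — Welch by default for
robustness, switchable to pooled variance to mirror classical software
defaults. Post hoc comparisons are paired t tests over all 36 state
pairs, Bonferroni-adjusted by default (the adjustment is configurable;
published orderings rarely name the method), rendered in the
`(i) > (j)` ordinal notation with consecutive ids compressed. Reported
tables round half away from zero to two decimals, the convention of the
emulated tables (0.275 → 0.28).

## Problem sizes and numerical choices

Simulation-backed checks use sizes chosen to make each check sharp yet
cheap: recovery runs average 20 seeds of 3 s continuous voiced stimuli
(about one second of analysis per stimulus); the null-calibration study
uses 1000 replicates of a reduced 10 + 10 cohort, which already pins the
rejection rate to ±1.4 % Monte-Carlo error; the end-to-end direction
check runs a 5 + 5-subject preset cohort with 6-word utterances and 5 %
scatter, ample for direction claims whose underlying cell-mean contrasts
are large. Degenerate inputs fail loudly and specifically: stereo or
truncated WAV files, infeasible pitch bands, silent input, fewer than
two subjects per group, singular within-subject covariance (epsilon
pinned to its lower bound with a warning).

## Known limitations

* The generator's source model is a stylized pulse train; spectral-slope
  and formant-related phenomena are out of scope, as are features beyond
  the seven (no MFCCs, no cepstral HNR).
* The intensity scale is convention-anchored, not SPL-calibrated.
* Unannotated velocity depends on energy segmentation and degrades for
  pauses shorter than `min_pause` plus one window.
* F statistics from any particular human dataset are not reproducible
  without that dataset; the statistical machinery is validated by
  oracle equivalence and calibration instead.
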