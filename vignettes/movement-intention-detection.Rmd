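---
title: "Detecting upper-limb movement intention from EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting upper-limb movement intention from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(moveintent)
```

## The problem

During self-paced reaching, the sensorimotor alpha (~8–13 Hz) and beta
(~15–30 Hz) rhythms over motor cortex lose power before the arm starts to
move — event-related desynchronization (ERD). A brain–machine interface that
recognizes this power drop can flag the *intention* to move before any overt
movement, shrinking the lag between a motor plan and the response of an
assistive or rehabilitation device.

`moveintent` implements the full offline pipeline for this problem on
cue-guided, self-paced reaching sessions: trials present "relax" (3 s), a
left/right move cue (12 s, movement self-initiated within it), and "rest"
(3 s) — 18 s per trial, 24 trials per block, 4 blocks per session. Because
the movement is self-paced, its onset is latent and must first be estimated
from EMG; everything downstream is referenced to that onset (`t = 0`).

The stages, each a module with its own functions:

1. **EMG onset labelling** (`emg_envelope()`, `detect_onset()`,
   `screen_and_realign()`): 10 Hz 6th-order zero-phase Butterworth high-pass,
   Hilbert-envelope magnitude, 200 ms moving average, z-scoring over the
   trial; the onset is the first zero upcrossing after the move cue that
   stays positive for 100 ms. Trials with onsets outside [3, 11] s post-cue
   are discarded; kept trials are re-referenced to the onset and trimmed to
   `[t_ini, 1]` s, `t_ini = -(onset + 3)`.
2. **Preprocessing** (`preprocess_session()`): keep the 9 motor-area
   electrodes (F3, Fz, F4, C3, Cz, C4, P3, Pz, P4), FIR-resample to 256 Hz,
   zero-phase 4th-order Butterworth band-pass 0.1–100 Hz, common average
   reference over the retained channels — in that fixed order, logged in the
   session provenance.
3. **ERD/ERS maps** (`compute_erds()`, `band_window_table()`): 7-cycle Morlet
   power at 2–40 Hz (1 Hz steps) on trials trimmed to [−6, 1] s;
   `ERDS(t,f) = 100 (TFR(t,f) − TFR_b(f)) / TFR_b(f)` against the [−6, −3) s
   baseline; per-cell significance by a trial-level percentile bootstrap
   (resample trials with replacement, recompute the map including its
   baseline, flag cells whose (α/2, 1−α/2) interval excludes zero).
4. **Features** (`burg_spectrum()`, `feature_vector()`): Burg AR(16) spectra
   of the causal window [t−T, t), evaluated at 8–25 Hz (18 integer
   frequencies covering alpha [8,14] and beta [14,25], the shared 14 Hz point
   counted once) per electrode — 162 dimensions, z-scaled with training-set
   statistics only.
5. **Detection** (`detect_movement_intention()`): RBF-SVM relax vs intention,
   trained on non-overlapping windows from the relax phase
   `[t_ini, t_ini + 3]` and the intention phase [−3, 0]; evaluated over 30
   random 80/20 trial-level splits with sliding windows every 0.1 s; chance
   levels from 30 runs with training labels permuted; Wilcoxon signed-rank
   (CA vs CA_sig) and rank-sum (DA(t) vs DA_sig(t)) at α = 0.01; the
   time-resolved metrics tMI and NT_D.

## The synthetic generator

No public recordings accompany this protocol, so `generate_session()` builds
sessions with the statistical structure the analysis assumes, plus ground
truth for parameter-recovery tests:

* onsets from N(7.04 s, 1.42² s²) truncated to [3, 11] s post-cue (rejection
  sampling), arms balanced within blocks;
* EEG = 1/f Gaussian background (exponent 1, sd 7 µV) split into a channel-
  independent and a shared component (30% shared variance, so the common
  average reference does nontrivial work), plus narrowband alpha ([8, 13] Hz,
  sd 10 µV) and beta ([15, 25] Hz, sd 8 µV) noise on the nine motor channels
  with independent phases per channel and trial;
* the rhythm amplitudes follow `erd_gain()`: a linear amplitude ramp from 1
  to `sqrt(1 − depth)` over the second before the true onset (power drops of
  0.40 and 0.20 by default), constant afterwards;
* EMG is band-limited noise (rest RMS 5 µV) whose RMS rises tenfold within
  50 ms of the onset on the moved arm.

Amplitude scales are the package's choice (the protocol does not fix them):
they put motor-channel band power in the oscillation-dominated regime typical
of awake EEG, so that a 40% drop in alpha oscillation power maps to a
measured band ERDS near −40%. The rhythms are narrowband *noise*, not
sinusoids: a deterministic sinusoid has no trial-to-trial power variability,
which would make the bootstrap degenerate, and a common phase across channels
would be annihilated by the common average reference.

Generation runs at 2048 Hz by default so the resampling stage is genuinely
exercised. Defaults reproduce the protocol (96 trials, 21 channels); tests
use smaller sessions and a 1024 Hz rate, which keeps every stage (including
4x decimation) in play. The test suite's problem sizes are: three 100-trial
generator seeds (twelve evaluation repeats) for the null calibration, three
96-trial seeds with the full 30 repeats for parameter recovery (the rank-sum
tests behind tMI lose power qualitatively below ~30 repeats), and one
96-trial session with 20 repeats per window length for the window-length
comparison; the acceptance script runs the full configuration (96 trials at
2048 Hz, 30 repeats, B = 1000).

What the generator does **not** emulate: ocular/muscular artifacts, volume
conduction, lateralization of the ERD (the protocol found none), and any
difference between the relax phase and the pre-onset period other than the
ERD itself. Passing tests therefore show the pipeline recovers its own
model's structure — they do not certify performance on real recordings.

## Numerical and design choices

* **Windows** are half-open `[a, b)` in samples; a window endpoint `t` maps
  to sample `floor(t * fs)`. The sliding grid is anchored at 1 s in 0.1 s
  steps so grids of different trials share time points.
* **Morlet width** is fixed at 7 cycles: at the 1 Hz grid this balances
  frequency resolution near the alpha band against time resolution around
  the onset. Cells whose wavelet support crosses a trial edge are flagged
  and excluded from baselines and significance.
* **Bootstrap** resamples trials (not samples), B = 1000 by default, one set
  of resamples shared across cells so maps are spatially coherent;
  percentile method. Under a null generator the flagged fraction stays near
  the nominal 5% (the suite checks ≤ 7%).
* **Burg fits** demean each segment first (the AR model has no intercept);
  the PSD normalization is one-sided, `2 σ² / (fs |A|²)` — only relative
  consistency matters because features are z-scaled afterwards.
* **Band/window summaries** average ERDS over *significant* cells only and
  print exactly 0 for windows with none, which reproduces the
  all-zero entries of quiet baseline windows; with few trials the selection
  inflates entries in quiet windows (only extreme cells pass), so those
  entries stabilize only at realistic trial counts.
* **RBF width.** The detector uses `k(u, v) = exp(-||u - v||² / (2 σ² D))`
  with σ = 0.5 and `D` the feature dimension. The width must scale with `D`:
  z-scored features put the typical squared distance near `2 D` (~320 here),
  so any fixed O(1) width collapses the Gram matrix to the identity and the
  classifier degenerates to a constant — measured accuracy sits exactly at
  chance. With the per-dimension width the same σ works for any montage
  size. Both σ and C (default 1) are configurable in `detector_config()`.
* **"Unequivocal" detection.** tMI is the earliest pre-onset grid time from
  which DA(t) rejects against DA_sig(t) at *every* grid point up to the
  onset and with DA above chance in mean — isolated spurious crossings do
  not count. NT_D counts test timelines with ≥ 3 consecutive intention
  outputs (0.3 s at the 0.1 s step) ending before t = 0; the run length is
  configurable. Both are explicit `NA` (not errors) when no sustained
  significance exists, which is exactly what a null session produces.
* **EMG onset rule.** "First value greater than zero" is applied to the
  z-scored envelope, but the search starts at the move cue and a 100 ms
  sustain guard is added: a whole-trial z-scored envelope inevitably
  wanders around zero during rest, and the guard preserves the rule's
  behavior on clean bursts while stabilizing it on noise. The z-score
  reference is the whole trial; a constant (burst-free) envelope is left at
  zero so it never crosses. Zero-phase filtering keeps the onset free of
  group delay.
* **Screening bounds** and the trim to `[t_ini, 1]` make every realigned
  trial cover [−6, 1] s, so the common ERD/ERS span drops nothing; the trim
  anchors at the trial's final sample (at 1 s up to one-sample quantization
  after resampling).

## Known limitations

* The pre-onset detection latency of the *generator* is conservative. In
  synthetic sessions the pre-onset EEG is statistically identical to the
  relax phase, so a classifier trained on relax vs [−3, 0] windows labels
  featureless pre-onset windows "relax" far more often than a permuted
  (chance) classifier labels them "intention": the time-resolved accuracy
  DA(t) sits *below* the permutation chance curve until the causal window is
  mostly filled with ERD. Sustained significance above chance is therefore
  reached only ~0.1–0.3 s before the onset, later than on real recordings,
  where relax and pre-movement EEG differ by more than the ERD (cue state,
  posture, attention). Emulating such state differences is out of the
  generator's scope.
* For the same reason NT_D saturates near 1: with ~60–100 pre-onset sliding
  windows per trial, three consecutive intention outputs occur in almost
  every trial at any realistic false-positive rate.
* The EMG burst morphology is a stand-in (band-limited noise with a step
  envelope); only its detectability by the high-pass + Hilbert procedure is
  calibrated.
* EDF export covers what this package writes (equal-length, cue-referenced
  trials concatenated per block, 16-bit, annotation markers); it is not a
  general EDF reader. The bundle format is the canonical lossless
  interchange.
* The alpha band is [8, 13] Hz in the ERD/ERS summaries but [8, 14] Hz in
  the feature grid; the two stages follow their own conventions on purpose
  and are not reconciled.
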