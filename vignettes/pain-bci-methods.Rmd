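---
title: "Methods: closed-loop pain detection from EEG and skin conductance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop pain detection from EEG and skin conductance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painbci)
```

## The problem

`painbci` implements a closed-loop brain-computer interface that detects
pain in real time from two neurophysiological signals — multichannel EEG
(500 Hz) over the centro-parietal cortex and palmar skin conductance
(SC, 5 Hz) — and releases a therapeutic intervention when pain is
detected. Two experimental regimes are covered:

* **Healthy / induced-pain protocol**: randomized painful (P),
  non-painful (NP) and rest (R) stimuli, 12 of each, 4 s stimulation time
  with an 8 s inter-stimulus interval. Offline recordings train
  per-subject decoders; online, the decoders run on streamed chunks and a
  fused decision is made every second.
* **Patient / focus-on-pain protocol**: 6 minutes of alternating 30-s
  rest and focus-on-pain blocks. Only EEG is decoded (SC carries no
  usable condition effect in this regime), and decisions are smoothed by
  a majority vote.

## Offline decoding model

The decoding path per modality is:

1. **Band-pass filtering.** EEG: 3–40 Hz linear-phase windowed-sinc FIR
   (Hamming window, order 2000). Offline the group delay (order/2 samples
   = 2 s at 500 Hz) is compensated so windows stay aligned to event
   markers; online the same filter runs causally with state carried
   across chunks, so a chunked stream reproduces one-pass filtering
   exactly. SC: 0.05–2 Hz Chebyshev type I, order 3, 0.5 dB passband
   ripple (the ripple value is not dictated by the protocol; 0.5 dB is
   the conventional default and is configurable). Both designs were
   cross-checked against an independent reference implementation; the
   Chebyshev coefficients agree to 10 significant digits.
2. **Running observation windows (ROWs).** EEG: 0.5 s with 80 % overlap
   inside each 4-s epoch, giving 36 windows of 250 samples per epoch;
   SC: 2 s with 80 % overlap (6 windows per epoch); patients: 1 s, no
   overlap. Windows are half-open `[start, start + length)` intervals
   and never cross an epoch boundary; each carries its source event id
   as a *group key*.
3. **Artifact rejection.** A window is dropped when the peak-to-peak
   amplitude of *any* channel exceeds 150 µV (EEG) or 10 µS (SC). The
   per-channel rule is deliberately conservative; the alternative
   (aggregate) rule would keep windows whose artifact is confined to one
   channel.
4. **Features.** EEG, per channel and concatenated over the six channels
   (60 columns): theta (4–7), alpha (8–13), beta (13–30), gamma
   (30–40) and total (3–40 Hz) band power from a Hamming-tapered
   periodogram zero-padded to 1024 points; peak frequency; sample
   entropy (m = 2, r = 0.2 SD); normalized spectral entropy; Higuchi
   fractal dimension (kmax = 10); RMS. SC (11 columns): mean, max,
   median, SD, variance, IQR, RMS, range, least-squares slope, median
   absolute deviation and trapezoid AUC against time. The AUC is
   computed on the signed band-passed signal: the 0.05–2 Hz filter
   removes the tonic level, making signed area the phasic-response
   readout. Beta/gamma band edges are not fixed by the protocol; 13–30
   and 30–40 Hz follow the conventional splits, with the upper edge
   bounded by the 40 Hz filter. The "total" band is computed on the
   filtered 3–40 Hz support.
5. **Classifier.** Features are z-scored (statistics estimated on the
   training split only; constant columns get SD 1 with a warning) and
   fed to a radial-kernel soft-margin SVM with C = 1, γ = 0.01. The
   dual problem is solved by an SMO solver with maximal-violating-pair
   working-set selection (validated against LIBSVM-based references:
   identical training accuracy, decision values agreeing to ~1e-3).
   Probability outputs come from a Platt sigmoid fitted on the training
   decision values — fitting on cross-validated decision values would be
   slightly better calibrated but needs five extra fits per machine; the
   online engine only thresholds the posterior, so the cheaper variant
   is used and documented here.
6. **Validation.** Stimulus-grouped four-fold cross-validation: whole
   stimuli (groups), not windows, are shuffled and dealt round-robin
   into folds, so overlapping windows of one stimulus never straddle the
   train/test split. The test suite demonstrates why: under label
   shuffling, window-level folds stay well above chance purely through
   leakage while grouped folds do not.

## Online engine

EEG is classified on every 0.5-s chunk and SC on a sliding 2-s window.
One deliberate deviation from the described 500-ms SC cadence: at 5 Hz a
0.5-s hop is 2.5 samples, which does not exist; SC therefore hops 1 s and
contributes one classification per decision period. Every second the
engine takes the most recent classifications in the last second (≤ 2 per
modality), averages pain posteriors within modality, and combines the
modality means with configurable weights (default 0.5/0.5; a missing
modality renormalizes). The intervention is released when the fused
posterior strictly exceeds 0.5 — an exact tie does not trigger — and a
release suppresses re-triggering for 10 s (one wave cycle of the
intervention). The exact fusion formula of the original system is
described only in supplementary material that is not part of the
available text, so this weighted-mean rule is this package's declared
default. Artifact-flagged chunks emit a no-decision marker and carry the
previous valid posterior forward (0 at stream start), keeping the
decision grid regular.

A painful event counts as detected if a trigger falls in
`(onset, end + 4 s]`; the window starts at onset rather than stimulus end
because a trigger during the 4-s stimulus is plainly correct detection.
NP and R events are correct iff no trigger falls in their window.

Patient mode classifies 1-s windows each second, takes the majority of
the last three labels (no output during the 2-s warm-up), splits each
30-s block into five 6-s chunks aligned to the block start (alignment is
a package choice; the protocol does not state one), and marks a chunk
released iff any in-chunk majority label is pain. Note what the majority
vote does and does not do: enumerating the vote windows shows it absorbs
isolated single-second blips but leaves a strictly alternating input
alternating — it is a debouncer, not a low-pass filter.

The modality-contribution statistic averages, over fused decisions that
correctly fired inside a P window, the weighted share of each modality's
mean posterior in the fused total. Using modality means rather than raw
member sums keeps the statistic invariant to the 2:1 EEG/SC
classification-count asymmetry, so equal posteriors give exactly (0.5,
0.5).

## Synthetic stated world

No public recordings exist, so the generator emulates the statistical
structure the decoders assume:

* **EEG** per channel: pink (1/f) background noise (SD 10 µV) + alpha
  (10 Hz, 2.5 µV) and beta (22 Hz, 3 µV) oscillators with random phase +
  white noise (SD 5 µV). During P epochs the oscillator amplitudes are
  scaled by (1 − 0.4) and (1 − 0.3) respectively (event-related
  desynchronization) and the white-noise SD by 1.3, which lowers
  narrow-band and total power and RMS while raising spectral/sample
  entropy and fractal dimension — the direction structure reported for
  induced pain. Transitions use 0.2-s raised-cosine ramps so the gate
  itself injects no broadband edge. Optional spike artifacts (default
  1/min, 300 µV, 50 ms) exercise the rejection path.
* **SC**: tonic 2 µS + slow drift + stimulus-locked double-exponential
  phasic response `amp · (e^(−t/2) − e^(−t/0.75))` after a 1.5-s
  latency, amp 1 µS for P and 0.1 µS for NP, plus measurement noise
  (SD 0.1 µS).

The condition effect sizes above are fixed by design; the free
background amplitudes were calibrated **once**, before any acceptance
test existed, so that default grouped-CV 2-class accuracy lands in the
empirically reported ranges (EEG ≈ 0.7, SC ≈ 0.83). Two constraints
pinned the corner cases: the beta oscillator must be strong enough
(3 µV) that its desynchronization outweighs the broadband power the
white-noise gain adds inside the wide 13–30 Hz band, otherwise beta
power would rise rather than fall during P; and SC noise of 0.1 µS keeps
the SC decoder better than, but within reach of, the EEG decoder.
Per-subject variability multiplies the effect sizes by U(0.8, 1.2).

What a green test does **not** establish: the generator has no head
model, no 1/f slope changes, no ocular/muscle confounds, no
autocorrelated SC noise, and its class-conditional distributions are far
better behaved than human single-trial data. Passing the recovery
criteria shows the *pipeline* is correct and well-calibrated on its
stated world, not that the reported human accuracies are reproduced.

## Feature-level statistics

Per-subject per-condition means (subjects are plotted as units in the
original analysis, and aggregation to subject means is the conservative
reading) enter a Friedman rank test (average ranks, tie-corrected
statistic) gated by Shapiro–Wilk normality; when the omnibus test
rejects, all-pairs rank-sum comparisons follow with the normal
approximation `SE = sqrt(nk(k+1)/6)` and Bonferroni adjustment over the
k(k−1)/2 pairs — the critical-difference procedure usually cited as
Siegel–Castellan, which the protocol names but does not define. Patient
mode uses a paired t-test with Cohen's d (mean/SD of differences) and
post hoc power from the noncentral-t distribution.

## Numerical choices and degenerate inputs

* PSD bins use half-open bands `lo ≤ f < hi`; peak-frequency ties break
  toward the lower frequency; an all-zero band yields spectral entropy 0
  and the lowest in-band peak frequency, with a message.
* Sample entropy counts template pairs at Chebyshev distance ≤ r with
  self-matches excluded; `A = 0` maps to the capped sentinel `log(B)`;
  a constant series gives 0 (and a flat series has Higuchi FD 1 by
  convention). The implementation is tested for exact equality against a
  naive O(n²) counting oracle.
* A pure 10 Hz sine's normalized spectral entropy under these PSD
  settings is 0.507 (frozen from an independent oracle) — the 250-sample
  window's zero-padded main lobe is wide — so "tone vs noise" contrasts
  are tested as orderings, not small absolute values.
* SD/variance are reported as `(sd, sd²)` so the redundant pair is
  exactly consistent; IQR quantiles use linear interpolation (type 7);
  MAD is the raw median absolute deviation (no 1.4826 consistency
  factor) since it feeds a classifier, not a robust scale estimate.
* `playback_stream` requires chunk length × sampling rate to be integral
  (tolerance 1e-6) and drops the final partial chunk, matching
  fixed-size online classification.
* EDF storage is 16-bit; the writer scales by the physical min/max *as
  written* in the 8-character header fields, so writer and reader agree
  exactly and the round-trip error is below one quantization step.

## Known limitations

* With the default strict-0.5 threshold and no hysteresis, the trained
  (non-oracle) online engine produces substantially more false triggers
  during rest than the original system reports; its supplementary
  probabilistic approach presumably included calibration or smoothing
  that the available text does not specify. The threshold, weights and
  refractory period are configurable.
* Platt calibration on training decision values is optimistic near the
  margins (see above).
* The EEG re-referencing question is left open in the source material;
  no re-referencing is applied here.
* Three-class probability outputs use averaged pairwise coupling, which
  is cruder than full pairwise-coupling optimization; only the 2-class
  posteriors drive the online engine.
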