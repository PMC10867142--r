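---
title: "Measuring and classifying cattle vocalizations with bovinecall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and classifying cattle vocalizations with bovinecall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dairy cattle produce two broad classes of vocalization: low-frequency (LF)
calls, emitted with the mouth closed or partly closed for close-range
contact, and high-frequency (HF) open-mouth calls used over distance and
associated with higher-arousal, typically negative, affective states. Both
call classes carry individual "voice fingerprints" — in the fundamental
frequency (F0) contour, call duration, amplitude modulation, and the
formant pattern imposed by the caller's vocal tract. `bovinecall` implements
the full desk stack for this kind of work: reading segmented call
recordings, measuring a standard set of 23 vocal parameters, classifying
call type and caller identity with an explainable stacked ensemble and with
a compact convolutional-recurrent network, and generating synthetic calls
with known ground truth so that every measurement can be validated.

## The 23 vocal parameters

The feature set follows the conventions of the cattle-bioacoustics
literature:

* **F0 statistics** — `F0Mean`, `F0Max`, `F0Min` over voiced frames and
  `F0Range = F0Max − F0Min` (computed, never re-estimated). Pitch is tracked
  by frame-wise normalized autocorrelation between a floor of 30 Hz and a
  ceiling of 1500 Hz (cattle can phonate above 1 kHz).
* **Spectral energy distribution** — `Q25`, `Q50`, `Q75` are the lowest
  frequencies at which the cumulative energy of the time-averaged power
  spectrum reaches 25/50/75%, and `Fpeak` is the frequency of maximum
  power.
* **`sound_duration`** — time between the first and last envelope frame
  within 25 dB of the envelope peak (an oscillogram-style gate); a `file`
  mode returns the whole file length for pre-trimmed corpora.
* **Amplitude modulation** — `AMVar` is the total variation of the dB
  envelope divided by the call duration (dB/s); `AMRate` counts envelope
  maxima with at least 2 dB prominence per second; `AMExtent` is the mean
  peak-to-adjacent-trough modulation depth in dB.
* **`harmonicity`** — the harmonic-to-noise ratio
  `10·log10(r/(1−r))` from the maximum normalized autocorrelation `r`,
  averaged over voiced frames.
* **Formants** — `F1Mean … F8Mean` from frame-wise Burg linear prediction
  (order 20, i.e. two poles per formant plus two spare pairs that absorb the
  glottal line and residual tilt) after pre-emphasis and resampling to twice
  the 10 kHz analysis
  ceiling; candidate resonances need a bandwidth below 600 Hz;
  `formant_dispersal` is the minimum spacing between consecutive formant
  means (inversely related to vocal-tract length).
* **`wiener_entropy_mean`** — mean over frames of the natural log of
  spectral flatness (geometric over arithmetic mean of linear power); 0 for
  a flat spectrum, strongly negative for tonal calls.

### Numerical choices in the pitch tracker

Pitch analysis runs at a decimated rate near 11 kHz with analysis windows of
`2/floor` seconds. Three details matter in practice and are worth stating:

1. The autocorrelation of a broadband harmonic call has peaks only about
   one sample wide at this rate, so the ACF is evaluated on a 4× finer lag
   grid via band-limited (sinc) interpolation before the parabolic
   refinement. Without it, short-period (high-F0) calls lose the true
   period peak to subharmonics.
2. A periodic signal peaks equally at every multiple of its period.
   Instead of a scalar octave cost, the tracker picks the *shortest*
   candidate lag whose peak is within 0.035 of the best one. This
   suppresses octave-down errors (equal-height subharmonic peaks differ
   only by noise, well under the tolerance) while a dominant partial —
   a call whose energy concentrates in one resonant harmonic — cannot
   capture the track, because its short-lag peak falls short of the true
   period's by more than the tolerance.
3. Voiced frames must also sit within 25 dB of the loudest frame, the
   track passes a width-5 median filter, and frames more than 0.8 octave
   from the call's median F0 are unvoiced. Onset and offset ringing (where
   the first formant briefly dominates) is removed by these guards.

The voicing threshold is 0.45 on the normalized autocorrelation peak.

### Numerical choices in the formant analysis

Formant estimation uses the textbook chain (pre-emphasis from 50 Hz,
resampling to twice the ceiling, Burg LPC, polynomial roots filtered by
bandwidth), with one automation: when 97.5% of the pre-emphasized energy
lies well below the nominal 10 kHz ceiling, the analysis band is narrowed
to about 1.15× the occupied bandwidth. This is the per-recording ceiling
adjustment every Praat practitioner performs by hand; without it, a call
whose eight formants all sit below ~6 kHz donates prediction poles to an
empty upper band and the low formants smear. Root pairs are reciprocals of
the AR poles, so bandwidth is `(fs/π)·ln|root|`.

Per frame the accepted resonances are sorted ascending and the first eight
fill slots F1–F8; `FkMean` averages slot k over the frames that offer it.
Slots never filled are reported as missing and the record is flagged;
flagged records are excluded from classifier training by default, mirroring
the quality-control culling of unusable calls in field datasets.

## The synthetic-call generator

`make_cow_profile()` draws a per-cow voice signature: base F0 per call type
(LF 70–120 Hz, HF 250–600 Hz), a uniform-tube formant spacing Δ (500–1300
Hz, so that F8 = 7.5Δ stays inside the 10 kHz analysis ceiling), an
amplitude-modulation rate (2–8 Hz) and depth (3–8 dB), call durations
(0.5–2.5 s, HF skewed longer), and a target harmonicity (18–28 dB).
`synthesize_call()` then realizes one call as a source-filter model:

* a harmonic glottal source follows a linear F0 ramp (drift up to ±25%
  within a call) with coherent (zero) harmonic phases, giving the
  pulse-like waveform of a real larynx and an unambiguous period;
* the vocal tract is an explicit magnitude envelope with one Lorentzian
  resonance per formant at `(2k−1)·Δ/2` and a −6 dB/octave source tilt.
  Additive synthesis under this envelope keeps every resonance peak exactly
  at its nominal frequency — a resonator cascade buries the upper formants
  under its own spectral tilt, and a parallel filter bank shifts composite
  peaks off their nominal centers, so neither can serve as ground truth;
* aspiration noise filtered by the same envelope enters at the drawn SNR,
  so harmonicity is controlled;
* a raised-cosine gate (20 ms edges) and sinusoidal AM shape the envelope,
  with 0.25 s of digital silence around the call.

Every drawn parameter is returned as a ground-truth record, making the
generator an oracle for the whole measurement chain. The default corpus
mix is 83.2% HF calls, matching the strong HF dominance of isolation
recordings, so class imbalance is exercised by every downstream test.

What the generator deliberately does **not** emulate: barn noise,
reverberation, overlapping callers, nonlinear phenomena (subharmonics,
deterministic chaos), within-call formant movement, or repertoires beyond
the binary LF/HF contrast. Tests passing on this corpus therefore show
definitional correctness of the measures and sound behavior of the
classifiers — not field robustness on farm recordings.

## The explainable classifier

The classifier is a bagged stack. For a training set:

1. `draw_subsamples()` draws r subsets (default r = 50) of 90% of the
   rows, repaired so every row appears in at least ⌈r/2⌉ subsets.
2. On each subset, three base families — a random forest, a regularized
   (glmnet) linear model, and a k-nearest-neighbour classifier — are each
   grid-searched under stratified inner CV, scored by the fold-averaged
   objective `Σ(aᵢ+fᵢ)/(2k)` (accuracy plus F1, averaged; 1 for a perfect
   classifier, maximized).
3. The three tuned bases produce *out-of-fold* class-probability
   predictions on the subset; a gradient-boosted tree meta-learner
   (xgboost; depth ∈ {2,3,4}, learning rate ∈ {0.05,0.1,0.3}, trees ∈
   {50,100,200}) is grid-searched on this meta table under the same
   objective and refit. Out-of-fold stacking is used because in-sample
   base predictions leak the training labels into the meta-learner.
4. Prediction is a majority vote over the r instances, ties broken by the
   largest probability summed across instances, then lexicographic label
   order — deterministic even for even r.

F1 is the classic positive-class score for the binary LF/HF task (HF
positive) and macro-averaged for identification. No resampling is applied
against class imbalance; stratification preserves the class ratio in every
fold. All randomness derives from one integer seed expanded into named
per-component streams.

`evaluate_stratified_kfold()` reports train and test accuracy as mean ± SD
over k = 5 stratified folds. `leave_one_feature_out_importance()` removes
one feature at a time, re-runs the whole harness, converts accuracy drops
(floored at zero) into percentages summing to 100, and returns the profile
sorted. If no drop is positive the profile is uniform — a deliberate
convention making "nothing mattered" visible.

## The spectrogram network

The deep model is a compact CNN+GRU: two 3×3 convolution blocks (16/32
channels by default, ReLU, 2×2 max-pooling) collapse the spectrogram's
frequency axis, the resulting sequence over time feeds a single-layer GRU
(64 units), and the final hidden state feeds a softmax. Input spectrograms
are min-max normalized per call and pooled to a configurable grid (200×64
by default). Training is Adam (10⁻³) on cross-entropy with early stopping
on a stratified validation split (patience 20), fully deterministic given
the seed. The implementation is base-R matrix algebra (im2col convolution,
backpropagation through time); its gradients are validated against finite
differences in the test suite, which is the property that matters for a
hand-written network.

## Problem sizes used by the tests and the acceptance script

The packaged experiments run at desk scale, chosen so the whole suite
completes comfortably on one CPU: the reference corpus is 5 cows × 40
calls (seed 7), ensemble evaluations in tests use the `"fast"` search
preset with r = 3 bags (r = 1, i.e. a single un-bagged stack, for the
23-feature importance sweep), and the network runs on a 64×32 grid with
8/16-channel blocks. The full-size defaults (r = 50, full grids, 200×64)
remain the exported defaults and are what a user with hours rather than
minutes should run. Accuracy at desk scale is conservative: more bags and
wider searches only help.

## Known limitations

* **High-F0 first formants.** When a call's fundamental approaches or
  exceeds F1 — common in high-frequency calls, where F0 can reach 600 Hz
  while F1 sits at 250–650 Hz — the F1 resonance is sampled by at most one
  weak harmonic and the call degenerates toward a single resonant partial.
  In that regime no frame-wise linear-prediction analysis can localize F1
  (the classic formant-undersampling limit), and the reported `F1Mean`
  inherits a bias of roughly 10–15% on affected calls; `F2Mean`–`F8Mean`
  are unaffected. The synthetic-corpus validation quantifies this: every
  other parameter recovers its ground truth within a few percent, while
  the F1 median error sits just above 10% because the profile ranges
  deliberately include such voices.
* The measures are definitionally faithful but not numerically identical
  to any particular Praat script: pitch/formant settings in field studies
  are rarely published, and two correct implementations of "Burg formants
  with a 600 Hz bandwidth cut" still differ in the third digit.
* The LF-only identification task can drop cows with fewer than k calls in
  the subset (logged, not fatal) — small LF corpora make this routine.
* The synthetic corpus is linear and clean; real isolation recordings
  carry noise floors and nonlinear phenomena the generator does not model.
* `wiener_entropy_mean` is capped at 0 per frame; machine-epsilon flooring
  of empty bins means silence does not produce −∞.
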