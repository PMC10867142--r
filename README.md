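# bovinecall

Quantitative analysis of dairy-cattle vocalizations in R: acoustic feature
extraction, call-type classification (low- vs high-frequency calls), and
individual-cow identification.

Cattle produce closed-mouth low-frequency (LF) contact calls and open-mouth
high-frequency (HF) calls associated with higher-arousal, typically
negative, states; both carry individual voice signatures in the F0 contour,
duration, amplitude modulation, and formant pattern. `bovinecall` gives
researchers and precision-livestock developers the full desk stack for this
kind of data:

* **Audio I/O** — RIFF/WAVE PCM reading/writing, manifest CSVs
  (`call_id,wav_path,cow_id,call_type`), Praat-style spectrograms
  (0.03 s Gaussian windows, 1000x250 grid, 60 dB range, 0-5000 Hz view) and
  RMS amplitude envelopes.
* **23 vocal parameters** per call: `F0Mean, F0Max, F0Min, F0Range, Q25,
  Q50, Q75, Fpeak, sound_duration, AMVar, AMRate, AMExtent, harmonicity,
  F1Mean ... F8Mean, formant_dispersal, wiener_entropy_mean` —
  autocorrelation pitch tracking, spectral energy quartiles, envelope
  modulation metrics, harmonic-to-noise ratio, Burg-LPC formants, and log
  spectral flatness.
* **An explainable classifier**: three grid-searched base families (random
  forest, regularized linear, k-NN) stacked into a gradient-boosted
  meta-learner, bagged over r = 50 coverage-guaranteed 90% subsamples with
  majority voting. Model search maximizes the fold-averaged objective

  `score = Σ_i (a_i + f_i) / (2k)`

  over k cross-validation folds (accuracy `a_i`, F1 `f_i`), and
  leave-one-feature-out importance turns accuracy drops into percentages.
* **A CNN+GRU spectrogram classifier** (two 3x3 conv blocks collapsing
  frequency, a GRU over time, softmax), written in base R and
  gradient-checked.
* **A source-filter call synthesizer** producing labelled cattle-like calls
  (per-cow F0/formant/AM/duration signatures, LF/HF contrast, known SNR)
  with exact ground truth for every parameter — the oracle behind the test
  suite.

## Worked example

```r
library(bovinecall)

# a labelled synthetic corpus: 5 cows x 40 calls, 83.2% HF
corpus <- synthesize_corpus(5, 40, hf_fraction = 0.832, seed = 7)
ft <- extract_feature_table(corpus$recordings)

# call-type classification, stratified 5-fold
res <- evaluate_stratified_kfold(feature_table(ft, "call_type"),
                                 k = 5, r = 3,
                                 control = ensemble_control("fast"), seed = 7)
print(res)
#> call_type / explainable, k = 5 folds
#>   train accuracy: 100.0 +/- 0.0 %
#>   test accuracy:  99.0 +/- 2.2 %
```

On this clean synthetic corpus the LF/HF contrast is fully separable (the
extracted `F0Mean` distributions do not overlap), so test accuracy is at or
near 100% — the print shows `mean +/- SD` over the five folds, the same
layout used for identification results (`feature_table(ft, "cow_id")`) and
for the deep model (`evaluate_grunet()`). On real farm recordings,
accuracies in the high-80s for call type and around 70% for identification
are typical.

```r
imp <- leave_one_feature_out_importance(feature_table(ft, "call_type"),
                                        k = 3, r = 1,
                                        control = ensemble_control("fast"),
                                        seed = 7)
head(imp$profile, 3)   # feature, importance_pct (sums to 100), acc_without
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/bovinecall synth --cows 5 --calls-per-cow 40 --seed 7 --out corpus/
Rscript inst/cli/bovinecall features --manifest corpus/manifest.csv --out features.csv
Rscript inst/cli/bovinecall evaluate --manifest corpus/manifest.csv --task callclass --preset fast --out results/
```

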