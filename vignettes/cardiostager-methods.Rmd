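---
title: "Sleep staging from instantaneous heart rate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep staging from instantaneous heart rate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

cardiostager scores every 30-second epoch of a night into four sleep
stages — wake, light (N1+N2), deep (N3/N4) and REM — using only the
instantaneous heart rate (IHR) derived from a single-lead ECG.  Cardiac
rhythm is strongly modulated by sleep stage, but the discriminative
signatures extend over minutes to hours (sleep cycles are 60–90 min long),
so the classifier must see both local beat-to-beat structure and very long
temporal context.  The package implements the full chain: R-peak detection,
IHR extraction and normalization, a fully convolutional network with
dilated temporal convolutions, training with a masked cross-entropy loss,
epoch-wise agreement metrics, hypnogram-derived sleep metrics, and the
covariate statistics used to relate those metrics to age, gender, apnea
severity and hypertension.  A synthetic-data module generates
stage-conditioned cardiac data so the entire pipeline is testable without
access-restricted polysomnography archives.

## Preprocessing

1. **R-peak detection** (`detect_r_peaks`) uses the Pan–Tompkins stages:
   band-pass filter 5–15 Hz, five-point derivative, squaring, 150-ms
   moving-window integration, adaptive dual thresholds with a 200-ms
   refractory period, and a search-back pass at half threshold.  Filtering
   is zero-phase (`signal::filtfilt`), so detections are refined to the
   local maximum of the filtered ECG without a group-delay correction.
   The 5–15 Hz band, 150-ms window and 200-ms refractory period are the
   classic values for this detector; nothing was re-tuned.
2. **IBI filtering** (`beats_to_ibi`): consecutive beat differences; a
   single pass removes intervals more than 5 standard deviations from the
   night's mean (both computed once over the raw series).  One pass, not
   iterated: the filter is meant to discard gross missed/spurious
   detections, not to sculpt the distribution.
3. **IHR input** (`ibi_to_ihr_input`): IHR = 1/IBI anchored at the later
   beat of each pair (causal assignment, standard in HRV work); per-night
   z-normalization computed on the beat-anchored values *before*
   resampling; linear interpolation onto a uniform 2 Hz grid; zero padding
   to 72,000 samples (10 h).  A validity mask marks the epochs actually
   covered by the recording.

Numerical edge cases: a zero-variance night yields all-zero normalized
values with a warning rather than an error (batch pipelines stay alive on
pathological records); recordings longer than 10 h are truncated head-first
with a warning.

A property worth knowing: because normalization happens on beat-anchored
values but the network input is uniform in time, slow rhythms are
over-represented after resampling.  For stationary or smoothly modulated
rhythms the resampled series keeps mean ≈ 0 and SD ≈ 1 (the test suite
checks 0.05 tolerances); for strongly stage-modulated nights the
time-uniform mean can sit a tenth of a standard deviation below zero.
This is a deterministic property of the stated normalization order, not
noise, and the network sees it consistently in training and inference.

## Network architecture

The input (72,000 samples) is cut into 1200 patches of 256 samples, one
per 30-s epoch, each centred on its epoch's centre (0-based epochs,
half-open windows, zero padding at the array bounds).  Patches overlap by
196 samples.

* **Local feature extractor**: three blocks, each two kernel-3
  convolutions with leaky-ReLU activations followed by max-pooling of
  stride 2; the block input is downsampled (stride-2 subsampling plus a
  kernel-1 projection) and added to the block output as a residual.  The
  channel plan 16→32→64 is the package's choice — the published
  description fixes the block structure but not the widths.  The final
  block's output is flattened and mapped by a learned 128-unit embedding
  layer ("embedding layer" rather than a bare reshape; a pure reshape
  would constrain channels × positions to exactly 128, which the
  architecture description does not do).
* **Dilated temporal stack**: two blocks of five kernel-7 convolutions at
  dilation rates 2, 4, 8, 16, 32 with leaky-ReLU activations, dropout
  (rate 0.2) after each block, and a block-level residual.  A single layer
  at dilation d spans (7−1)·d+1 epochs: 13 epochs (6.5 min) at d = 2 and
  193 epochs (96.5 min) at d = 32, so the stack covers everything from
  within-epoch structure to a full sleep cycle.  The dilated channel width
  equals the embedding width so residuals add without projection.
* **Output head**: kernel-1 convolution with 4 filters and a per-epoch
  softmax → 1200 × 4 row-stochastic probabilities.  The predicted
  hypnogram is the per-epoch argmax; ties break to the lowest class index
  (wake < light < deep < REM) so decoding is deterministic.

Remaining conventions the description leaves open, fixed here: "same"
zero padding everywhere (lengths are preserved exactly, which also makes
the network translation-equivariant — shifting the input by one epoch
shifts interior predictions by one position); leaky-ReLU slope 0.01;
He-style weight initialisation; dropout only in the dilated stack (the
published text mentions it only there).  Batch normalization is accepted
as a configuration flag but rejected when enabled, since the final model
configuration does not use it.

The network is implemented in C++ (RcppArmadillo) with im2col + GEMM
convolutions and hand-derived backpropagation; the test suite verifies the
analytic gradients against central finite differences and the patch/shape
arithmetic against closed forms.

## Training

Masked cross-entropy: the mean of −log p(reference class) over valid
epochs only; epochs in the zero-padded region and unscored reference
epochs contribute nothing.  The published recipe — 10^6 steps, batch 2,
learning rate 1e-4, "L1 weight decay 0.25", dropout 0.2 — is the default
configuration.  Two readings of the decay rate are possible; the raw-sum
reading makes 0.25 overwhelm the cross-entropy for any realistic network,
so the package applies the coefficient to the *mean* absolute
convolutional weight (penalty = 0.25 · Σ|w|/N over conv and projection
weights, excluding biases and the embedding layer), which keeps it
scale-comparable with the loss.  The optimizer is Adam with default
moments (the original does not name one; Adam is the standard choice for
this architecture family).  Training is deterministic given the seed
(batch sampling, initialisation and dropout all derive from it).

## The reduced experiment preset

CPU-scale experiments (the test suite and `scripts/acceptance.R`) use
`model_config(preset = "reduced")`: 128-sample patches, channel plan
2/4/8, width-16 embedding, one dilated block — 11,620 parameters instead
of the full configuration's 1.44 million — trained 10,000 steps at batch 1 and learning
rate 1e-3 on 60 simulated nights, evaluated on 20 held-out nights.
These problem sizes are the package's own choice of a configuration that a
single CPU trains in roughly ten minutes while still exercising every
architectural element (patching, residual local blocks, the full dilation
ladder, masked loss, dropout).  With the well-separated easy emission
preset the held-out four-class accuracy is far above the 0.25 chance
level; this checks that the pipeline can learn, not that the reduced model
matches full-scale published performance.

## Synthetic data

`simulate_hypnogram` builds nights as sequences of 60–90-min cycles
(lengths drawn from a clamped normal, mean 80 min, SD 10 min).  Within a
cycle, stage bout durations are gamma-distributed (shape 8) around targets
derived from night-level stage fractions — defaults: light 0.55, deep
0.20, REM 0.25 of sleep, efficiency 0.88, typical adult values — with
deep sleep front-loaded and REM back-loaded through geometric cycle
weights that are normalised so night-level expectations are unchanged.
Wake bouts are inserted at up to three positions per cycle.  Because the
weights are normalised and the integerisation is randomized rounding, the
expected occupancy of each stage equals its target analytically, which is
what makes the statistical recovery tests sharp.  Durations are
bout-explicit (a semi-Markov construction) rather than epoch-wise Markov,
so bout-duration statistics — in particular mean REM bout length and its
fragmentation — are directly controllable.

`simulate_night_ibi` emits beat-by-beat intervals at a stage-conditioned
rate: per-stage means default to wake 72, light 61, deep 55, REM 66 bpm
(the canonical wake > REM > light > deep ordering), with per-stage
short-term variability, a slow sinusoidal oscillation, broadband noise and
outlier (stretched) intervals emulating missed beats.  The `"easy"`
preset (means 76/62/51/69, small variability) is deliberately generous —
it is used for learnability experiments; `"hard"` narrows the separations
for robustness work.  `simulate_ecg` places a Gaussian QRS-T template at
each beat with baseline wander and white noise, returning ground-truth
beat times for round-trip checks of the detector.

`simulate_cohort` samples covariates independently per night (frequencies
default to a large community cohort's composition) and shifts each night's
stage-fraction and efficiency targets linearly in the covariates.  Effect
sizes are therefore expressed directly in metric units and the expected
metric of a night is linear in its covariates with exactly the configured
coefficients — so regression recovery can be tested for bias and CI
coverage, not just sign.  Apnea is modelled only through its hypnogram
signatures (stage-fraction shifts and REM fragmentation), never through
airflow, which the method never sees.

What the generator does *not* emulate: real HRV spectra (respiratory
sinus arrhythmia, LF/HF structure), scorer disagreement in the reference
labels, artefact-laden ECG segments, or correlations between covariates.
Passing tests therefore demonstrate pipeline correctness and statistical
calibration under a favourable, known emission model — not clinical
performance, which requires the restricted polysomnography datasets.

## Evaluation and clinical statistics

`evaluate_hypnograms` pools every scored epoch as an independent
prediction: accuracy, Cohen's kappa ((p_o − p_e)/(1 − p_e) with chance
agreement from the confusion-matrix marginals), a 4 × 4 confusion matrix
(rows = reference), and per-night accuracy/kappa.

`compute_sleep_metrics` derives light/deep/REM fractions (of sleep
epochs), sleep efficiency (non-wake fraction of *scored* epochs — the
definition is not universal; this package uses the full scored recording
as the denominator, the main interpretive risk when comparing against
studies that use time-in-bed after sleep onset), and the mean REM bout
duration (maximal runs of REM, in minutes).

The covariate battery follows the two-stage published design exactly:

1. Rank tests on the raw metrics — Wilcoxon rank-sum (normal
   approximation, tie-corrected) for binary covariates, Kruskal–Wallis for
   polychotomous ones — at a Bonferroni-corrected threshold.  The divisor
   is m = 16 (4 metrics × 4 covariates), the package's reading of "the
   battery"; it is configurable.
2. Sequentially adjusted OLS: metric ~ age + gender (ordinal integer
   codings: age classes 0–3, female 0/male 1); residuals regressed on
   apnea class (0–3); those residuals regressed on hypertension (0/1).
   "Adjusted" is implemented as residuals (not coefficient subtraction);
   with independently sampled covariates the two coincide in expectation.
   Per pair the report carries the coefficient, 95% CI, p-value and
   100·R² (from the single-covariate fit at that pair's adjustment
   stage).  A pair is flagged significant only when *both* the rank test
   and the regression cross the corrected threshold — the dual criterion
   also keeps the family-wise false-positive rate conservative, which the
   test suite measures over 200 null cohorts.

The REM-bout variant restricts to apnea classes 0, 1 and 3 (keeping the
class codes, so severe stays 3), first tests whether age contributes
alongside gender and drops it when not significant, adjusts for the
retained covariates, and regresses the adjusted bout durations on apnea
severity.

## Problem sizes used by the checks

The test suite and acceptance script run entirely on synthetic data:
150–200 nights for occupancy calibration, one 400-night cohort for effect
recovery, 200 replicate cohorts (n = 120) for coefficient bias and CI
coverage, 200 null cohorts (n = 80) for the family-wise error rate, a
20-minute 250-Hz ECG for the detector round trip, and the reduced
60/20-night training experiment described above.

## Known limitations

* The network must see a full night (1200 epochs) at once; it is not a
  streaming scorer.
* The EDF/WFDB readers and writers cover the single-channel 16-bit subset
  this package produces and consumes, not the full formats.
* Deep-sleep occupancy of the generator has a small (≈2% relative)
  downward ratio bias from per-cycle duration noise; tolerances in the
  calibration tests account for it.
* No record-quality scoring or exclusion is performed anywhere in the
  pipeline, by design.
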