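---
title: "Methods: automatic intelligibility and severity assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic intelligibility and severity assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathospeech)
```

## The clinical problem and the model

Speech intelligibility (INT) and speech-disorder severity (SEV) are the two
perceptual measures used in the follow-up of patients treated for head and
neck cancer. Both are scored on a 0–10 scale, where 0 is unintelligible
speech with high severity and 10 is perceived unimpaired speech; in clinical
practice the reference value is the mean over a panel of expert judges.
Panel scoring carries intra- and inter-rater variability, which motivates an
automatic replacement.

This package predicts both scores from a recording of a standard French
passage-reading task (the first paragraph of *La chèvre de M. Seguin*,
returned verbatim by `canonical_passage()`). The pipeline has two learned
stages:

* **Speaker embedding (x-vector).** Frame-level log-mel features pass
  through five time-delay (dilated 1-D convolution) layers; a statistics
  pooling layer concatenates the per-dimension mean and standard deviation
  over frames, converting arbitrary-duration input to a fixed vector; two
  fully connected segment-level layers follow. The embedding is the affine
  (pre-activation) output of a designated segment layer and has 512
  dimensions for any input.
* **Shallow multi-task regressor.** Two hidden blocks, [emb × 128] and
  [128 × 64], then two affine heads [64 × 1] predicting INT and SEV
  jointly. The two measures are highly correlated perceptually; joint
  training through a shared trunk exploits that correlation.

The loss is the equally weighted sum of per-task mean squared errors,
`0.5 * MSE(INT) + 0.5 * MSE(SEV)`, optimized by Adam with learning rate
0.001, batch size 8, dropout 0.2, for exactly 20 epochs (no schedule, no
weight decay, no early stopping). These values are the deployed recipe and
are the `training_config()` defaults.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| sampling rate | 16000 | Hz | standard ASR rate; recorders at 48 kHz are downsampled |
| mel filters | 24 | — | common x-vector front end |
| frame length / shift | 25 / 10 | ms | standard framing |
| embedding dim | 512 | — | fixed by the extractor architecture |
| dropout | 0.2 | — | deployed recipe |
| learning rate / batch / epochs | 0.001 / 8 / 20 | — | deployed recipe |
| loss weights | 0.5, 0.5 | — | equal task weighting |
| tempo factors | 0.9, 1.1 | — | mild distortion; see below |
| pause threshold | −35 | dBFS | endpointing default, configurable |
| minimum pause | 150 | ms | endpointing default |

## Design choices where the design was open

**Hidden-block ordering.** "ReLU after each layer" with batch norm and
dropout admits several orderings, and applying ReLU to the scalar heads
would forbid negative pre-activations while breaking gradients near 0
targets. We use linear → batch norm → ReLU → dropout on the two hidden
blocks (the common recipe) and affine heads with inference-time clamping to
[0, 10]. Train mode uses batch statistics and inverted dropout; inference
uses running statistics (momentum 0.1) and no dropout, and is deterministic.

**Embedding tap.** Practice differs on which segment layer the embedding is
taken from. The default taps the affine output of the *last* fully connected
layer; `extractor.tap_layer = "first"` (the `tap` argument of
`extract_embedding()`) switches to the first segment layer. Both satisfy the
512-dimension contract; neither is asserted to be the original system's
choice.

**Passage segmentation.** Recordings are cut into eight segments at natural
breaks in the text to multiply training samples. The exact break points are
a reconstruction: the four sentence boundaries after sentence 1 plus the
three major clause commas of sentence 3, positioned in time by cumulative
character fraction and snapped to detected pauses (RMS below −35 dBFS for at
least 150 ms). Breaks are matched to pause midpoints by an order-preserving
minimum-total-mismatch assignment; a greedy nearest-pause rule can drift and
exhaust the pause list, which is why the small dynamic program is used. With
exactly seven detected pauses it reduces to using all pauses in order.
Explicit cut times are always available as an override.

**Tempo augmentation.** The augmentation class is time-scale modification
preserving pitch and spectral envelope; we implement waveform-similarity
overlap-add (WSOLA, Hann windows of 512 samples at 50% overlap, ±128 sample
tolerance), which needs no vocoder model. The distortion amounts are not
prescribed anywhere; the default factor set {0.9, 1.1} is deliberately mild
so that tempo changes do not plausibly alter perceived severity, and
augmented copies inherit the source segment's labels. The algorithm is
deterministic; the `seed` argument exists only for interface stability.

**Relative energy floor.** Filterbank powers are floored at `1e-7` times the
utterance maximum (≈70 dB dynamic range) in addition to an absolute floor of
`1e-10`. Without it, digitally silent frames sit ~30 log units below speech,
and because utterance mean normalization redistributes that outlier across
all frames, appending even 100 ms of silence would move the embedding by
several hundred percent. With the relative floor, silence behaves like a
quiet frame and the documented padding-insensitivity bound (<10% embedding
change for 100 ms of appended silence on passage-scale input) holds. Pure
digital silence still maps exactly to the configured absolute floor.

**Inference aggregation.** Scoring a recording defaults to embedding the
whole passage (`strategy = "whole"`); `strategy = "segments"` averages the
eight per-segment predictions. Which one the original deployment used is
unknown; both are exposed, and a speaker-disjoint split utility
(`split_speakers()`) prevents augmented copies from straddling
train/validation boundaries.

**ICC convention.** Inter-rater reliability uses the two-way model with
absolute agreement, computed from the ANOVA mean squares. The `average`
(panel-mean, ICC(A,k)) form is the default because the clinical reference
score is the judge-panel mean; `single` (ICC(A,1)) is exposed. Negative
ANOVA estimates are reported as computed unless `floor_negative = TRUE`. The
statistic accepts any complete numeric matrix; the 0–10 range check applies
only to the `ratings_matrix` constructor used for instrument data. Published
panel ICCs for this task are not re-derived: the underlying rating matrices
are private.

## The synthetic cohort: what it emulates and what it does not

Clinical corpora for this task are private, so every learned component is
validated on synthetic cohorts with known ground truth
(`sample_cohort(cohort_spec(...))`):

* SEV is drawn uniformly on [0, 10] — real cohorts skew impaired but
  publish no distribution, and a uniform support maximizes the power of
  rank-based checks; INT is SEV plus Gaussian coupling noise (sd 1 by
  default, giving the high INT–SEV correlation seen perceptually), both
  clamped to [0, 10] after noise, matching the bounded instrument.
* Embeddings are `u1·INT + u2·SEV + nuisance + N(0, 0.5)` with fixed
  orthonormal directions: linear-plus-noise *by design*, so ordinary least
  squares on the two signal directions is an analytic ceiling and "the
  network learned the signal" is a checkable claim.
* Judge panels are `clamp(true + bias_j + error_ij)` with six judges and
  unit bias/error variances by default, the classic two-way variance
  components that the ICC estimator must recover.
* `synth_passage_audio()` builds eight harmonic bursts separated by >300 ms
  silences whose harmonic-to-noise ratio degrades as severity decreases —
  enough structure for the segmentation, feature, and embedding plumbing to
  be exercised end to end.

A green parameter-recovery test (held-out Spearman ≥ 0.9 at 200 training
speakers, noise sd 0.5, the deployed recipe, five seeds) establishes that
the training loop, loss, and architecture can extract a planted monotone
score-to-embedding relationship. It does **not** establish clinical
performance: synthetic embeddings are linear in the scores, contain no
channel or microphone effects, no session variability, and no pathological
acoustics. The published clinical correlations are properties of private
corpora and are out of scope here.

## Numerical notes

* Statistics pooling uses the population standard deviation and is exactly
  permutation invariant; pooling a matrix concatenated with itself equals
  pooling the matrix.
* Resampling is rational-factor polyphase with a windowed-sinc low-pass
  (10 zero-crossings per side); resampling at the current rate is the
  identity, making the operation idempotent.
* Segment times are half-open intervals `[start_s, end_s)`; sample index
  `floor(t * rate)` — concatenating a recording's segments reproduces the
  spanned region sample-for-sample.
* Batch normalization uses eps `1e-5`; a partial final mini-batch is kept
  (with batch statistics over however many examples it holds).
* Training validates targets to [0, 10] and raises a divergence error
  naming the epoch if the loss becomes non-finite.
* Seeded operations snapshot and restore the caller's RNG state, so package
  calls never perturb user-level reproducibility.
* Extractor weights round-trip bit-exactly through RDS at run time; the
  portable interchange format is a manifest plus one TSV per layer at 17
  significant digits.

## Known limitations

* Seeded random extractor weights are a test double; meaningful clinical
  scores require externally trained weights (`import_weights_tsv()`).
  Training the extractor on speaker-verification corpora is out of scope.
* Pause-based segmentation assumes the reader pauses at clause boundaries;
  read-through speakers will trigger a segmentation error rather than a
  silent mis-cut (by design).
* The monitoring store is plain text; encryption and multi-user access
  control are deployment concerns outside the package.
* No automatic speech recognition, forced alignment, noise reduction, or
  uncertainty quantification.
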