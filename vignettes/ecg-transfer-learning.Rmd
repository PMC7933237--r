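---
title: "Methods: pretraining and transfer for ECG classification at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pretraining and transfer for ECG classification at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecgtl)
```

## The problem and the approach

Record-level ECG classification — for example deciding whether a short
single-lead recording shows atrial fibrillation (AF) — suffers from small
annotated data sets, because expert labels are expensive. The workflow
implemented here transfers knowledge from a large corpus of continuous
single-lead ECG: a 1D convolutional encoder is pretrained on one of four
objectives defined over short signal *frames*, and the resulting weights
initialize a downstream classifier that is finetuned end-to-end on the
small target task.

The four pretraining objectives differ in how much annotation they need:

* **Beat classification** uses expert beat annotations. A frame is labeled
  with the most frequent abnormal beat class inside it (premature atrial
  contraction, premature ventricular contraction, aberrant conduction), or
  *normal* if no abnormal beat is present.
* **Rhythm classification** uses expert rhythm intervals. Per-class
  durations are the overlap of each rhythm interval with the frame; AFib
  and AFlut are prioritized — if either overlaps the frame at all, the
  longer of the two wins — otherwise the longest of the remaining rhythms
  (normal sinus rhythm or noise) is used.
* **Heart-rate classification** needs no human labels at all: beats are
  located (ground-truth annotations, or the package's QRS detector), the
  rate is estimated from interbeat intervals, and the frame is labeled
  bradycardia (< 60 BPM), normal (60–100 BPM, both ends inclusive),
  tachycardia (> 100 BPM) or noise when no rate is estimable. The frame
  is temporarily extended by 1 s on each side before labeling, so very
  short frames get a more stable rate estimate; the model still only sees
  the frame itself.
* **Future prediction** is self-supervised contrastive predictive coding:
  the model must identify the true future frame among negatives sampled
  from the corpus, which forces the encoder to extract structure shared
  between a context and its future.

All four are cast as classification and minimize categorical
cross-entropy with Adam at its default hyperparameters (learning rate
1e-3, β₁ = 0.9, β₂ = 0.999).

## Model architecture

The encoder is a 1D pre-activation residual network (normalization →
nonlinearity → convolution). Depths 18 and 34 use basic blocks; depth 50
uses bottleneck blocks that expand stage width fourfold. Stage filter
sizes are 7, 5, 5 and 3, larger than the classical 3×3 because ECG
features (P/QRS/T complexes) span tens of samples at 250 Hz. The stem is
a kernel-7 stride-2 convolution followed by a stride-2 max-pool; stages
2–4 downsample by 2 at entry; features are pooled by global averaging.
Weights use He-style normal initialization. `width_multiplier` scales all
stage widths (default 1.0 = 64/128/256/512 channels); desk-scale runs use
0.125.

For future prediction, the encoder's frame encodings of the K context
frames are summarized by *attention pooling*: a learnable context token
`c0` is prepended, the sequence passes through N = 3 Transformer encoder
layers (8 heads, feed-forward width 2·d_model, no dropout, post-layer
normalization), and the output at the token position is the context
vector `c`. Similarity with each candidate encoding `h_i` is the plain
(unscaled) dot product; a softmax over candidates gives the probability
that candidate i is the true future. Design choices where the design was
genuinely open:

* *Positional information.* Future prediction is order-sensitive, so
  learned positional embeddings are added to the pooled sequence (token at
  position 0). A flag disables them, which makes the pooled vector
  provably invariant to context permutations — the test suite uses this to
  verify the attention implementation numerically.
* *No similarity temperature.* The dot product is left unscaled, matching
  the plain contrastive formulation.
* *Truncated pretraining of the deepest net.* Contrastive pretraining of
  the depth-50 encoder would quadruple the attention width; the package
  supports building only the first `stages_used` stages, pretraining
  those, and freshly initializing the remaining stage at finetuning.

The numerical core (convolution and max-pooling kernels in compiled code,
batch normalization, dense layers, multi-head attention, Adam) is
implemented in the package; every backward pass is verified against
finite differences in the test suite.

## Pretraining protocol

Patients are split by identity: validation patients (5% by default, at
least one) never contribute a training frame, which the implementation
tracks by provenance and the tests assert. Frames are sampled patient-
uniformly (then segment, then position), and standardized with mean and
standard deviation computed once over the entire corpus — not per frame.
Every `checkpoint_interval_steps` (default 2000, much smaller in
desk-scale runs) the task accuracy on a fixed validation set is recorded;
after training, the model reverts to the checkpoint with the highest
validation accuracy, ties resolving to the earliest step. For the
contrastive task the validation metric is positive-identification
accuracy. `max_steps` is an explicit budget knob: at full scale the
sampling budget is 4096 frames per training patient (≈ 42.8 million
frames for 10,450 patients), far more than a desk-scale run uses.

Tie-breaks are fixed for reproducibility: beat-count ties resolve by the
priority PVC > PAC > aberration; an AFib/AFlut duration tie resolves to
AFib; an NSR/noise tie to NSR. Frames with no annotated beat are
unlabelable for the beat task (it has no noise class) and are resampled.
Heart-rate "failure to detect" is implemented as fewer than two beats in
the padded window, since the rate estimator needs at least one interbeat
interval; the 1 s pad is clipped at segment boundaries rather than
discarding the frame. The BPM estimator is 60 / mean(IBI) — the simplest
unbiased choice consistent with labeling from interbeat intervals.
Contrastive negatives may come from anywhere in the corpus, including the
positive's own segment, excluding only windows that overlap the positive.

## Finetuning and evaluation

Downstream records are standardized with statistics over the entire
downstream set — this mirrors the transfer protocol being modeled, and
the train/test leakage it implies is deliberate and confined to two
scalars. Records are resampled to the upstream rate (250 Hz) by polyphase
rational resampling (zero-stuffing, a delay-compensated windowed-sinc
low-pass at the tighter Nyquist limit, decimation) and right-padded with
zeros to a uniform 60 s; longer records (possible only in synthetic
profiles) are tail-truncated. Lower-rate experiments keep the same
relative length (60 s × target rate).

The classification head is replaced by a freshly initialized fully
connected layer (softmax for single-label, sigmoid with binary
cross-entropy for multi-label); training is end-to-end with nothing
frozen. Training stops early when training accuracy has not strictly
improved for 50 epochs (cap 200); weights revert to the epoch with the
best validation macro F1 (single-label) or best validation loss
(multi-label). `repeated_evaluation()` fixes a stratified 20% test set
and repeats the finetune 10 times with fresh train/validation draws from
the remaining 80%, reporting mean ± sd per metric. Stratification uses
per-class largest-remainder allocation, so every split's class count is
within one record of the exact proportion; classes too small to appear in
every non-empty split are rejected with a message. A fold-based split
(folds 1–8 / 9 / 10) is available as the alternative mode used by
fold-annotated multi-label corpora.

Metrics: macro F1 (a class absent from both truth and prediction scores
0); one-vs-rest rank-based AUC with midranks, averaged over classes with
at least one positive and one negative; sample-centric Fmax over a
threshold grid (default 0 to 1 in steps of 0.01; precision averaged over
samples with at least one predicted label, recall over all samples); and
the class-averaged challenge scores F(β=2) = 5·TP / (5·TP + FP + 4·FN)
and G(β=2) = TP / (TP + FP + 2·FN), computed after a per-metric threshold
search on training scores (ties take the smallest threshold). The G-score
definition follows the challenge evaluation code it generalizes from (a
Jaccard measure with missed positives weighted by β); classes with a zero
denominator contribute 0. All metric implementations are checked against
brute-force confusion-matrix and pair-counting oracles.

## The synthetic-data generator

The generator's purpose is *testability*, not physiological realism: it
produces signals whose class structure is exactly known, so every labeler
and training stage can be verified against planted ground truth. A beat
is a Gaussian QRS bump with smaller P and T bumps; PVCs are widened,
high-amplitude, P-free and followed by a compensatory pause; PACs arrive
early; aberrant beats are widened with an inverted T wave. AFib episodes
have log-normal interbeat intervals with a high coefficient of variation
(default 0.25) and no P waves — AF learnability rests on exactly the
irregularity that defines it clinically. Noise episodes are band-limited
noise with no beats. Rhythm episodes follow a Markov chain; amplitudes
are arbitrary units (standardization removes scale). One global seed
drives splitmix-style per-patient child seeds, so corpora are
reproducible piecewise.

Two parameter sets matter:

* `gen_params()` — the general defaults: per-patient baseline rate
  uniform in 50–110 BPM, 3% NSR jitter, AFib at 110 BPM mean with CV
  0.25, flutter at 150 BPM, abnormal-beat rates 5%/5%/2%.
* `gen_params_separable()` — the preset used by the desk-scale training
  checks, chosen once: baseline rates from a pool well away from the
  60/100 BPM class boundaries (42–136 BPM), long NSR-dominated episodes,
  AFib at 130 BPM (clearly tachycardic), and per-patient beat morphology
  (QRS width/amplitude, T and P wave size). The morphology gives
  contrastive pretraining a patient fingerprint that the context shares
  with its future but not with cross-patient negatives — the property
  that makes the future-prediction task learnable by a tiny encoder in
  minutes. Downstream records draw a fresh morphology per record, since
  each record represents a different subject.

What passing tests on this generator do and do not show: they demonstrate
that the pipeline's mechanics are correct (labels match planted truth,
training reduces the intended loss, transfer moves information between
stages) and that each task is learnable when its class signal is present.
They do not show clinical-grade performance: real ECG has electrode
artifacts, baseline wander, morphological variability within patients,
and far subtler class boundaries than the separable preset. Scores
obtained on synthetic corpora are not comparable to scores on real
challenge data.

## QRS detection

`detect_beats()` is a deliberately simple energy detector: band-pass
5–15 Hz (2nd-order Butterworth, zero-phase), squared derivative, 150 ms
moving-window integration, a threshold at 25% of the envelope peak and a
200 ms refractory period, with peak positions refined on the band-passed
signal. Before accepting any beats the envelope must look impulsive
(peak ≥ 8× its median); pure-noise segments fail this gate and return an
empty result. On clean synthetic sinus rhythm its sensitivity exceeds
0.95 with timing within 40 ms; it is not a clinical detector and
wavelet-grade detectors are out of scope.

## Desk-scale problem sizes

The package's own checks use sizes chosen so that each stage demonstrates
its property within minutes on one CPU, stated here as the package's
standard desk-scale configuration:

* upstream corpus: 30 patients × 1 segment × 60 s at 250 Hz, separable
  preset;
* supervised pretraining: width 0.125 depth-18 encoder, 512-sample
  frames, batch 32, 800 Adam steps, checkpoints every 100 steps, 10%
  validation patients;
* contrastive pretraining: K = 8 context frames of 512 samples, offset 2,
  ns = 4 negatives, batch 8, 700 steps (chance = 0.2);
* downstream: 100 synthetic single-lead records (class ratios
  0.4/0.2/0.2/0.2), preprocessed to 60 s at 250 Hz;
* the pretrained-vs-random comparison at epoch 5 uses a
  0.55/0.25/0.20 train/validation/test split rather than the protocol's
  0.75/0.05/0.20: at 100 records a 5-record validation set quantizes
  macro F1 too coarsely to measure an early-epoch gap, so the comparison
  enlarges validation while the protocol split stays the default
  everywhere else;
* the repeated-evaluation shape check runs 10 finetune repetitions at 2
  epochs each.

## Known limitations

* Waveforms are schematic; no 12-lead vectorcardiographic geometry — the
  12 leads of the multi-label profile are scaled copies of one source
  with independent noise.
* The attention pool processes one batch element at a time in R; it is
  sized for desk-scale contexts (K ≤ 63).
* Fβ/Gβ class weighting is per-class averaging; the upstream challenge's
  confusion-weighted variant is out of scope.
* Training is single-device and single-precision-agnostic (R doubles);
  there is no GPU path.
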