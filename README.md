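# ecgtl — transfer learning for ECG arrhythmia classification

Deep networks classify raw ECG well when tens of thousands of annotated
recordings are available, but most ECG data sets — especially those from
wearable, single-lead monitors — are small, because expert beat and rhythm
annotation is expensive. `ecgtl` implements a transfer-learning workflow
for this setting: a 1D convolutional encoder is first *pretrained* on a
large corpus of continuous single-lead ECG (using labels that are cheap or
free to produce), then *finetuned* end-to-end on a small record-level
classification task such as atrial fibrillation (AF) detection.

The package is aimed at method developers who want to experiment with ECG
pretraining objectives and transfer protocols on a laptop: every stage runs
at desk scale on synthetic corpora with exact, planted ground truth, so the
full pipeline — corpus generation, weak labeling, pretraining, channel
adaptation, finetuning, repeated evaluation — is testable without any
download or GPU.

## What is inside

**Synthetic annotated corpora.** `generate_upstream_corpus()` renders
continuous 250 Hz single-lead recordings per patient: Gaussian-bump beat
templates (P/QRS/T), a Markov chain of rhythm episodes over
NSR/AFib/AFlut/noise, per-patient baseline heart rate and beat morphology,
and exact beat/rhythm ground truth. AFib is irregular by construction (high
interbeat-interval coefficient of variation, absent P waves).
`generate_downstream_set()` emulates two downstream shapes: short
(9–60 s) single-lead 300 Hz records with one label among
{NORMAL, AF, OTHER, NOISY}, and 10 s 12-lead 500 Hz multi-label records.
Corpora are written as WFDB records (`.hea`/`.dat` + MIT-format beat
annotations) with rhythm intervals in a JSON-lines manifest.

**Pretraining tasks.** Frames (half-open sample windows; 512/2048/4096
samples at 250 Hz) are sampled patient-uniformly and standardized with
corpus-level statistics. Four objectives:

- *beat classification* — most frequent abnormal beat class in the frame
  (PAC / PVC / aberration), else normal;
- *rhythm classification* — longest overlapping rhythm, prioritizing AFib
  and AFlut;
- *heart-rate classification* — bradycardia (< 60 BPM), normal (60–100),
  tachycardia (> 100) or noise, from interbeat intervals in the frame
  padded by 1 s on each side (beats from ground truth or a Pan–Tompkins
  style detector, `detect_beats()`);
- *future prediction* — contrastive predictive coding: K consecutive
  encoded context frames are pooled by a small Transformer (learnable
  context token `c0`, N = 3 layers, 8 heads, feed-forward width
  2·d_model) into a context vector `c`, and the model must identify the
  true future frame (at a configurable frame offset) among `ns` negatives
  by the softmax over dot products `c·h_i`.

**Models.** 1D pre-activation residual encoders (depths 18/34/50, stage
filter sizes 7/5/5/3, bottleneck blocks at depth 50, optional stage
truncation, He initialization), with a `width_multiplier` for desk-scale
runs. The neural-network core — convolution/pooling kernels (compiled),
batch normalization, multi-head self-attention, Adam — is implemented in
the package. `adapt_input_channels()` transfers a single-lead encoder to
12-lead input by duplicating first-layer filters and rescaling by 1/12,
which reproduces the single-lead output exactly on replicated input.

**Transfer protocol.** `run_finetune()` replaces the classification head,
trains end-to-end (nothing frozen) with early stopping on training
accuracy and checkpointing on validation macro F1 (single-label) or
validation loss (multi-label). `repeated_evaluation()` fixes a 20% test
set, resamples train/validation from the remaining pool, repeats the
finetune n times and reports mean ± sd of the test metrics: macro F1 with
per-class F1, class-wise AUC, sample-centric Fmax, and the challenge
F(β=2) / G(β=2) scores with per-metric threshold search.

## Worked example

```r
library(ecgtl)

corpus <- generate_upstream_corpus(4, segments_per_patient = 2,
                                   segment_duration_s = 60,
                                   gen_params = gen_params_separable(),
                                   seed = 7, dir = "demo_corpus")
print(corpus)
#> <ecg_corpus: 8 recordings from 4 patients, 480.0 s total>
print(corpus$recordings[[1]])
#> <annotated_recording p00000/s00: 60.0 s @ 250 Hz, 69 beats, 1 rhythm intervals>

label_frames(corpus, "heart_rate", frame_length = 512, n = 8, seed = 1)
#>   recording_id start length       task  label
#> 1   p00000_s01  4774    512 heart_rate NORMAL
#> 2   p00000_s01  9724    512 heart_rate NORMAL
#> 3   p00002_s00  8461    512 heart_rate  TACHY
#> ...
```

The first patient's 60 s segment carries 69 annotated beats at its
baseline rate; the frame labeler reads 512-sample (~2 s) windows, pads
them by 1 s per side, and classifies the interbeat-interval rate — patient
`p00002` has a tachycardic baseline, so its frames label `TACHY`.

At full scale, reserving 5% of 11,000 patients for validation and sampling
4096 frames per training patient yields the pretraining budget:

```r
budget <- sampling_budget(10450, 4096)
budget_millions(budget)
#> [1] 42.8   # million frames
```

Pretraining and finetuning follow the same API at any scale:

```r
spec <- model_spec(18, width_multiplier = 0.125)   # desk-scale ResNet-18
cfg  <- pretrain_config("heart_rate", frame_length = 512, max_steps = 800,
                        checkpoint_interval_steps = 100, seed = 11)
pre  <- run_pretraining(corpus, spec, cfg)         # best-checkpoint model

dset <- generate_downstream_set(100, "cinc2017", seed = 5)
fcfg <- finetune_config(max_epochs = 10, n_runs = 3, seed = 7)
data <- prepare_downstream(dset, fcfg)
report <- repeated_evaluation(pre$model, data, spec, fcfg)
```

A command-line front end (`exec/ecgtl`) wraps the same functions:
`ecgtl generate`, `ecgtl label`, `ecgtl pretrain`, `ecgtl finetune`,
`ecgtl evaluate`.

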