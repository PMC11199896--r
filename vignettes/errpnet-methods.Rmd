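---
title: "Classifying error-related potentials with errpnet: model, training strategy and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying error-related potentials with errpnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Error-related potentials (ErrPs) are stereotyped EEG responses evoked when a
person perceives an error — their own, a machine's, or an external agent's.
An error epoch typically shows a sharp fronto-central negativity (the
error-related negativity, Ne) some 200–350 ms after the eliciting event,
followed by a positivity (the error positivity, Pe). Detecting ErrPs on
single trials enables error-aware brain–computer interfaces, but single-trial
EEG has poor signal-to-noise ratio and its statistics drift across subjects,
recording sessions and experimental paradigms. ErrP corpora are also small
and heavily imbalanced (roughly one error per four to five correct trials),
which starves deep classifiers of training data.

`errpnet` packages a complete treatment of this problem:

1. a canonical **preprocessing pipeline** that reduces heterogeneous
   recordings to `(2, 64)` epochs — two fronto-central channels (FCz and Cz,
   with Fz substituting for FCz where the montage lacks it), 1–10 Hz
   zero-phase Butterworth band-pass, event-locked windows of one trial
   duration, downsampling to 64 samples per epoch, and a ×1,000 amplitude
   expansion;
2. a **dual-branch convolution + transformer network** classifying each
   epoch as error or correct;
3. a **transfer-learning training strategy** — pretrain on an existing
   paradigm's data, fine-tune on a small amount of target-paradigm data —
   with leakage-safe SVM-guided oversampling (SVMSMOTE) inside stratified
   K-fold cross-validation;
4. the five **evaluation protocols** used in the cross-subject ErrP
   literature (within-session, cross-session, leave-one-subject-out,
   one-train-one-test, cross-task), with accuracy, AUC and per-class
   detection rates;
5. a **synthetic ErrP generator**, so that every stage is exercisable and
   testable without downloading EEG corpora.

## The model

Each input epoch is a `2 × 64` matrix (electrodes × samples). Two parallel
feature extractors read it in complementary ways.

**Electrode branch (FE-E).** The epoch is treated as a sequence of two
electrode tokens. A 64-filter `(1, 33)` valid convolution extracts local
temporal features per electrode (width 64 → 32), average pooling `(1, 4)`
widens the receptive field (32 → 8), and a second 64-filter `(1, 8)`
convolution collapses the temporal axis (8 → 1), so that each electrode is
summarized by the 64 filter activations. These two 64-dimensional electrode
tokens pass through a transformer encoder layer (4 heads, model width 64)
whose self-attention captures the interaction between the electrodes.

**Time branch (FE-T).** The epoch is treated as a sequence of sampling-point
tokens. A 64-filter `(2, 33)` convolution collapses the electrode axis while
extracting cross-channel features (output width 32), and average pooling
`(1, 16)` downsamples the time positions to 2 — matching the electrode
count so the two branches fuse cleanly. The resulting two 64-dimensional
time tokens pass through their own transformer encoder layer.

In both branches the encoder output is added to the encoder input through an
extra residual connection (in addition to the residuals inside the encoder
layer) and layer-normalized. The two `(2, 64)` token maps are concatenated
(FE-E first), flattened to 256 features, and classified by two
fully-connected layers (256 → 64 → 2) with dropout after each, ending in a
softmax. Batch normalization follows every convolution. The default network
has 156,482 trainable parameters (`count_parameters()`).

```{r, eval = FALSE}
library(errpnet)
net <- build_network(model_config(), seed = 1)
x <- array(rnorm(8 * 2 * 64), c(8, 2, 64))
p <- forward(net, x, with_trace = TRUE)
attr(p, "trace") # every intermediate tensor shape
```

### Architectural choices the description leaves open

Several details are under-determined by the architecture's published
description; `errpnet` fixes them as follows and treats them as part of its
own design:

* **Activations.** ReLU after each convolution's batch norm, and inside the
  encoder feed-forward block. Standard practice for this layer pattern.
* **Encoder internals.** Post-norm transformer encoder, feed-forward width
  256 (4 × the model width), no internal dropout, layer normalization (not
  batch normalization) inside the encoder.
* **No positional encoding.** Both token sequences have length 2 and their
  order is already injected by the convolutions; adding sinusoidal codes
  would change the model class without textual support.
* **Pooling.** Non-overlapping average pooling (stride = kernel), forced by
  the published shape chain (32/4 = 8, 32/16 = 2).
* **Dropout rate 0.5** after both classifier layers, inactive at inference.
* **Fusion order.** FE-E tokens before FE-T tokens; the flatten is
  token-major (token 1's 64 features first). Any fixed order yields the
  same model class; one is fixed for reproducibility.
* **Class convention.** Index 0 = correct, 1 = error; reported scores are
  error-class probabilities; the decision threshold is 0.5.

## The training strategy

**Pretraining** uses SGD with momentum 0.9, initial learning rate `1e-4`,
batch size 32, 200 epochs, label smoothing ε = 0.1, and cosine decay of the
learning rate, stepped once per epoch from `1e-4` at epoch 0 to 0 at the
final epoch: η(t) = lr_min + ½(lr_init − lr_min)(1 + cos(πt/T)).
Stratified 5-fold cross-validation splits the pretraining corpus; the model
carried forward is the fold model with the highest final validation
accuracy (ties broken by lower final validation loss — "best" is otherwise
unspecified, and validation accuracy is the headline metric).

**Class balancing.** Before each fold's training run — never on the full
corpus, and never on validation or test partitions — the minority (error)
class is oversampled to exact balance with SVMSMOTE: an RBF-kernel SVM
(cost 1) locates the decision boundary; its minority support vectors seed
synthetic samples, interpolated toward one of their 5 nearest minority
neighbors when the seed's 10-neighborhood is majority-dominated ("danger"),
or extrapolated away by at most 0.5 of the neighbor distance otherwise.
These four knobs match the reference implementation's documented defaults,
which the method's description adopts without setting values. The feature
space for the SVM fit and the neighbor search is the flattened
128-dimensional epoch, unstandardized (inputs are already ×1,000-scaled);
the description never states the oversampling space, and the flattened
epoch is the simplest reversible choice.

**Fine-tuning** continues training of *all* weights (no freezing is
mentioned, so none is applied) on the target participant's full data with
Adam at `1e-5` — ten times below pretraining — for 100 epochs under the
same cosine decay, with no internal validation split: fine-tuned models are
evaluated on *other* participants only. Oversampling during fine-tuning is
off by default (the strategy describes oversampling in the
cross-validation context only); it can be enabled via the `oversample`
argument.

```{r, eval = FALSE}
pair <- generate_task_pair(
  synth_config(task = "speller", seed = 1),
  synth_config(task = "cursor", seed = 1,
               task_shift = list(amplitude_scale = 0.8,
                                 latency_offset_s = 0.03,
                                 noise_multiplier = 1.25)))
cv <- pretrain(pair$source)                       # stratified 5-fold CV
net <- best_network(cv)
subj1 <- pair$target[pair$target$info$subject == "s01"]
ft <- finetune(net, subj1)                        # all weights, Adam 1e-5
```

## The evaluation protocols

All protocols report accuracy, AUC (probability that a random error epoch
outscores a random correct one, ties credited ½; computed by midranks,
which is exactly the pairwise count), and the per-class detection rates,
in percent.

* **Within-session** — train, validate and test inside one participant's
  one session via stratified 5-fold CV; the cell value is the mean over
  held-out folds. The granularity (per participant rather than pooled) is
  this package's choice, matching the per-participant style of the
  standard reporting tables.
* **Cross-session** — select a model on session A by CV, test on session
  B; both directions reported.
* **Leave-one-subject-out** — within one session, train on all remaining
  participants (CV model selection, pretraining-phase optimizer settings)
  and test on the held-out participant.
* **One-train-one-test** — train on a single participant (CV model
  selection, fine-tuning-phase optimizer settings) and test on every other
  participant; this is the non-pretrained baseline for transfer.
* **Cross-task** — pretrain on the source task, fine-tune one copy of the
  single best pretrained checkpoint per target participant, test each on
  the remaining participants, and pair every column with its
  one-train-one-test baseline.

Which session of a two-session corpus feeds the single-session protocols is
left to an explicit `session` argument (the source material does not say).
Every runner records index provenance — which epochs trained and which were
tested — and the test suite asserts that no test epoch ever reaches a
training partition, including through oversampling (synthetic rows are
generated from training rows only, by construction and by audit).

A pooled-covariance linear discriminant (`lda_baseline()`, pseudo-inverse
fallback for singular covariance) on the flattened epochs provides a
classical reference point.

## The synthetic generator

`generate_epochset()` emulates the statistical structure the method
assumes, directly at canonical shape (no continuous-EEG synthesis, no
forward head model):

* **Morphology.** Error epochs carry a Gaussian-windowed negative bump
  followed by a positive bump; correct epochs carry background noise only.
  Defaults: Ne at 260 ms (width 40 ms, −0.010 ≈ −10 µV on the ×1,000
  volt scale), Pe at 380 ms (width 60 ms, +0.012), channel gains (1.0,
  0.8). The published material is qualitative about amplitudes and
  latencies, so these are free parameters chosen from typical ErrP
  literature values, not claims about any real corpus.
* **Imbalance.** Error fraction 0.205, the prevalence of the reference
  observation-ErrP corpus (1,322 / 6,437); class counts are exact per
  subject and session: `round(0.205 × n)`.
* **Population.** 6 subjects × 2 sessions × 537 epochs by default,
  mirroring the reference corpus layout. Per-subject variability jitters
  the latencies (sd 20 ms) and scales the amplitudes (sd 15%).
* **Noise.** 1/f-shaped ("pink") background by spectral shaping of white
  noise, sd 0.005 (≈5 µV) per sample. This makes the default
  single-trial SNR more favorable than real EEG, where it is usually
  below 1 — deliberately, so that desk-scale training budgets can
  demonstrate the pipeline's behavior. Passing tests on this generator
  show the machinery is correct, not that real-data accuracies transfer.
* **Task shift.** `generate_task_pair()` derives source and target
  streams from one seed; the target's template is modified by a global
  amplitude scale, a latency offset and a noise multiplier — a
  deliberately simple, controllable model of cross-paradigm shift. Real
  paradigm differences (montages, trial durations, artifact profiles,
  non-stationarity within sessions) are not modeled.
* **Degraded subjects.** A preset (template ×0.05, noise ×2) reproduces
  the known failure mode of a participant whose recordings carry almost
  no discernible error signal, for which cross-subject accuracy
  collapses.
* **Determinism.** One top-level seed; per-subject and per-session streams
  are derived by stable hashing, so outputs are bit-identical regardless
  of generation order.

## Numerical choices

* **Zero-phase filtering.** Whether the original preprocessing filtered
  causally or zero-phase is unstated; `errpnet` filters forward–backward,
  the standard offline ERP practice, which preserves Ne/Pe latencies. The
  band-pass is applied as a cascade of analytically designed second-order
  sections: a single 8th-order recursion for a 1–10 Hz band at 512 Hz is
  numerically ill-conditioned (linearity residuals near 1e-4), while the
  cascade is exact to ~1e-13. Short odd-reflection padding suppresses edge
  transients. Filtering happens on the continuous recording, before
  epoching, wherever continuous data exists.
* **Downsampling** is plain decimation for integer rate ratios — the
  preceding 1–10 Hz band-pass already prevents aliasing at 64 Hz — and
  polyphase resampling otherwise. Epoch windows are half-open
  `[onset, onset + duration)` with 0-based onsets, fixing exact sample
  counts.
* **Batch norm** uses batch statistics in training and running statistics
  (momentum 0.1, unbiased running variance) at inference, making
  inference deterministic and batch-composition independent.
* **The epoch store** keeps amplitudes as IEEE float32 — ample for
  ×1,000-scaled EEG — so a reload reproduces the float32-quantized values
  bit-exactly and save/load is idempotent from the first cycle.
* **Degenerate inputs.** Single-class test sets yield `NA` AUC with a
  warning; a noiseless class collapses to duplicate points, which the
  oversampler and SVM handle (synthetic points coincide with the seeds);
  non-finite training loss aborts with a diagnostic rather than
  continuing.
* **Reproducibility.** Every stochastic component (generator, fold
  assignment, SMOTE, weight init, batch shuffling, dropout) draws from a
  stream derived from a single seed by stable hashing; fixed seeds give
  bit-identical training trajectories on a fixed platform.

## Scale of the validation experiments

The test suite validates the expensive properties at reduced problem
sizes, chosen as the smallest scales at which the properties are
meaningful: perfect recovery of a noiseless separable problem runs the
full 200-epoch pretraining budget on one subject's 80 epochs; the
transfer-benefit experiment (pretraining on a shifted source task improves
held-out-subject accuracy over training from scratch) uses 10 seeded
replicates of a 2-subject × 250-epoch source and 4-subject × 100-epoch
target with 20 pretraining and 20 fine-tuning epochs and 2-fold
cross-validation in the pretraining stage. Directional properties
(transfer benefit, noise monotonicity) are averaged over seeds and tested
non-strictly; point properties (shape chain, oracle equivalences,
leakage) are exact.

## Known limitations

* The published accuracies on the three public EEG corpora are not
  reproduced here: they require the external downloads. The MAT ingestion
  hook (`ingest_mat()`) reads MAT v7.3 containers and knows the three
  dialects' sampling parameters, but the internal variable layout of each
  distribution must be confirmed against the actual files before that
  path is trusted.
* The generator's Gaussian-bump morphology and global-shift transfer model
  are idealizations; no artifact rejection, re-referencing or baseline
  correction is implemented because the canonical pipeline performs none.
* Binary classification only; inputs other than `(2, 64)` are a
  configuration-time error, except through `model_config()`'s explicit
  shape parameters.
* Training runs on the CPU in plain R with two small C++ kernels; it is
  intended for the corpus sizes of this literature (thousands of epochs),
  not for large-scale EEG.
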