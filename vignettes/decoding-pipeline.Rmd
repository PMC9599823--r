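---
title: "Decoding visual stimuli from fMRI: the ROI-CNN + residual GCN pipeline"
author: "gcndecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding visual stimuli from fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcndecode)
```

## The decoding problem

A subject views one of ten stimulus categories while being scanned; each
stimulus block yields three whole-brain EPI volumes (TR 3 s) on a
64 x 64 x 50 grid of 3 mm voxels. The task is to predict the category from
that block. Whole-brain classifiers waste capacity on regions that carry no
visual information, so the pipeline restricts itself to eleven visual
regions of interest: the retinotopic areas V1d, V1v, V2d, V2v, V3d, V3v
("low-level" group), plus V4, LOC, FFA, PPA and HVC ("medium/high-level"
group). HVC is deliberately the voxel-wise union of LOC, FFA and PPA and is
processed as an eleventh, overlapping region; its voxels are extracted
independently of its constituents, and nothing downstream down-weights the
duplication.

The model has two stages:

1. **Per-ROI 3D CNN streams.** Each ROI-masked scan (the full grid with
   everything outside the mask zeroed; the three frames enter as channels)
   passes through its own nine-layer 3D CNN: convolutions C1-C6 with
   kernels 5 x 5 x 3 (C1-C5) and 3 x 3 x 3 (C6) at stride 1, max-poolings
   S1-S3 with kernel 3 and stride 2 after every second convolution, batch
   normalisation and ReLU after every convolution, channel schedule 16, 16,
   32, 64, 64, 8, no padding anywhere. Output extents follow
   `floor((I + 2P - D(K-1) - 1)/S) + 1`; iterating that rule collapses
   64 x 64 x 50 to exactly 1 x 1 x 1 with 8 channels, so the stream's
   feature vector is simply the flattened final activation — no extra head
   is needed, and `shape_chain()` exposes the closed-form calculation that
   the tests compare against real forward passes. Stacking the eleven
   streams gives the 11 x 8 feature matrix. The eleven streams share an
   architecture but not weights (a `shared_weights` switch exists for
   ablation).

2. **Residual GCN over the ROI graph.** ROIs are graph nodes; edges carry
   functional connectivity. With `A` the 11 x 11 adjacency,
   `Atilde = A + I` and `Dtilde` its row-sum degree matrix, one graph
   convolution is `H_out = ReLU(Dtilde^-1/2 Atilde Dtilde^-1/2 H W)`. The
   classifier stacks five blocks of dropout(0.5) -> graph convolution ->
   batch norm -> ReLU with residual connections, then flattens the 11 x 8
   node features and applies one fully connected layer to produce the ten
   class scores.

## The connectivity graph

Edge weights are group-weighted Pearson correlations,
`a_ij = w_ij P(r_i, r_j)` with `w_ij = omega` (default 3) when both ROIs
are in the same group, 1 across groups and 0 on the diagonal. Two choices
here are ours, because the construction is underdetermined:

* **What signals enter `P`.** Each scan contributes only three time points
  per ROI, statistically meaningless on their own. We correlate each ROI's
  mean time course concatenated across all *training-subject* scans,
  compute the adjacency once per experiment, and freeze it for training and
  inference. Computing it on test subjects would leak; a test asserts the
  frozen adjacency equals one recomputed from training scans only.
* **Negative correlations.** `Dtilde^-1/2` requires non-negative
  generalised degrees, and nothing specifies a sign convention, so `|P|` is
  used by default; `signed = TRUE` disables this and then normalisation may
  legitimately fail with a clear error.

`omega` is configurable with default 3, and sweeping it (for instance over
1.5-4.0) needs no more than a loop over `run_experiment()` calls;
`adjacency = "plain_pearson"` and `"random"` reproduce the ablation
controls.

## Residual wiring

With `Z = BN(Ahat %*% dropout(H) %*% W)`, the three implemented wirings are
type B (default) `ReLU(Z + H)`, type A `ReLU(Z) + H`, and type C
`ReLU(Z + H Wproj)` with a trained projection; `none` removes the skip (the
no-residual-connection ablation). The three labels do not determine unique
topologies, so these definitions are this package's concrete
instantiations: pre-activation addition for B, post-activation for A,
projection for C. The skip adds the block *input before dropout*, so the
identity path is never masked. Hidden width is constant (8) across blocks
so identity skips are always dimension-valid. A property test verifies the
motivating phenomenon: with eight stacked blocks and no skips, inter-node
feature variance collapses (over-smoothing) relative to type B.

## Training

The CNN streams and the GCN train jointly: one cross-entropy loss
(softmax + negative log-likelihood, mean over the batch), one backward pass
through the GCN into all eleven streams, Adam on every parameter. Defaults: 200 epochs, learning rate 0.01, weight decay
0.001, batch size 16, dropout 0.5. Weight decay is applied as an L2 term
added to weight-matrix gradients (classical Adam + L2, not decoupled decay)
and is not applied to biases or batch-norm parameters. The validation
subject selects the best checkpoint by loss; no early stopping. Splits are
subject-wise: in trial `t` of the five-trial protocol, subject `t` is the
test subject, the next subject in cyclic order validates, and the remaining
three train. Argmax ties break toward the lowest class index.

Every backward pass in the package is hand-derived and checked against
central finite differences end to end (masking -> conv/BN/ReLU/pool
streams -> all residual types -> both heads) to relative error below 1e-5
in the test suite, and the Adam update path is covered by a
parameters-change test; training determinism is asserted by re-running a
fit and comparing loss histories exactly.

## The synthetic generator

No imaging data ships with the package; `generate_template()` and
`generate_dataset()` create datasets with exactly the structure the decoder
assumes:

* ten disjoint ellipsoidal ROI blobs placed in separate compartments of the
  grid (100-600 voxels each at full resolution, scaled with grid volume,
  minimum 8), HVC their union;
* a fixed spatial pattern `P(c, r)` per class and ROI with per-voxel
  amplitudes of mean `effect_size * noise_sd` (relative spread
  `pattern_sd`, default 1, so patterns discriminate classes voxel-wise);
  HVC inherits its constituents' voxels rather than adding a second
  pattern, because its mask is exactly their union;
* a frame-wise gain (0.8, 1.0, 0.9) emulating a hemodynamic ramp — the
  frames act only as channels, so no richer temporal model is warranted;
* a multiplicative log-normal per-subject gain (SD `subject_gain_sd`,
  default 0.1) motivating the per-subject normalisation step;
* i.i.d. Gaussian voxel noise, `noise_sd` 1.

Defaults mirror the study conditions: 5 subjects, 10 classes, 20 scans per
class per subject, effect size 2. One master seed fans out to a derived
sub-seed per (subject, class, repetition), so datasets regenerate
bit-identically and any single scan can be reproduced in isolation.

What the generator does *not* emulate: hemodynamic convolution,
physiological or structured noise, motion, EPI distortion, anatomical
variability between subjects, or class imbalance. Passing tests therefore
show that the implementation recovers structure the model assumes, not that
the model would reach any particular accuracy on real acquisitions.

"Same range" normalisation of subjects is not pinned down by the source
description; we use per-subject z-scoring (each subject's own global mean
and SD over all its scans — so no statistics cross subjects) and expose
min-max scaling as the alternative.

## Desk-scale configuration

The full-resolution architecture trains in minutes per epoch on a GPU but
not on one CPU core, so the test suite and examples use a scaled
configuration chosen once: grid 12 x 12 x 10 with the `"small"` preset (two
3 x 3 x 3 convolutions, two 2 x 2 x 2 poolings, feature width 8), which
collapses to 1 x 1 x 1 exactly like the nine-layer original. Everything
else — Adam, learning rate 0.01, weight decay 0.001, batch 16, dropout 0.5,
five subjects, twenty scans per class, effect size 2 — is unchanged, with
20 epochs instead of 200 (the loss plateaus long before that at this
scale). Under these conditions the pipeline reaches >= 90% accuracy on the
held-out subject, label-permuted training stays at chance, and the no-GCN
and no-residual ablations do not beat the full model; the full-resolution
path itself is exercised by forward-pass shape and finiteness tests.

## Numerical choices

* Batch norm uses biased variance for normalisation and for the running
  statistics (momentum 0.1, eps 1e-5); inference uses running statistics,
  dropout is inference-inert, so prediction is deterministic.
* Initialisation is seeded He-uniform (bound `sqrt(6/fan_in)`); biases,
  beta start at zero, gamma at one.
* Convolutions run through im2col + BLAS GEMM when the unfolded matrix is
  small enough, and through a direct loop kernel otherwise; both paths are
  tested against each other and against explicit loop oracles.
* Cross-entropy uses the log-sum-exp form; `0.5` probabilities give
  0.6931 as expected.
* Undefined precision/recall (zero denominator) is reported as 0 with an
  `undefined` flag so macro averages stay defined.
* Constant signals have no Pearson correlation: an error by default, 0
  with a warning if requested.

## Limitations

* The residual wirings A/B/C are explicit stand-ins for topologies that
  their labels alone do not determine; B is the default.
* The adjacency's source signals are our stated assumption (see above).
* The classifier head is one fully connected layer; a deeper head is
  conceivable but unstated in the source description.
* Benchmarking on real acquisitions (the OpenNeuro ds001246 recordings
  this design targets) is out of scope: it needs the download and GPU-scale
  training.
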