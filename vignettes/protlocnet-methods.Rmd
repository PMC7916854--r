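---
title: "Classifying protein subcellular localization with CNN and FCN heads: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying protein subcellular localization with CNN and FCN heads: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-throughput immunofluorescence imaging annotates each stained protein
with the subcellular compartments its signal occupies. Samples are
four-channel confocal images — green for the protein of interest, blue for
the DAPI-stained nucleus, red for anti-tubulin microtubules, yellow for the
endoplasmic reticulum — and each sample carries one to four of 13 organelle
classes (actin filaments, centrosome, cytosol, ER, Golgi, intermediate
filaments, microtubules, mitochondria, nuclear membrane, nucleoli, nucleus,
plasma membrane, vesicles). Because proteins multilocalize, this is a
multi-label image classification problem.

`protlocnet` implements two closely related deep classifiers over a shared
convolutional trunk, the automatic generation of spatial training targets
for the fully convolutional variant, the full training protocol, per-class
confidence-threshold calibration by dice maximization, and a multi-label
evaluation suite. Because the package must be testable without a
20,000-image microscopy corpus, it also ships a synthetic fluorescence
simulator that generates images with exact ground truth.

## Architectures

The base trunk is five blocks of [conv 3×3 → ReLU, conv 3×3 → ReLU, batch
normalization, max-pool 2×2], with the kernel count doubling after every
pooling stage — ten convolutional layers in total. Two heads specialize it:

* **CNN**: flatten + three fully connected layers, the last with 13
  sigmoid outputs, one confidence per class. Dropout sits between the
  fully connected layers.
* **FCN**: the final max pool is removed (so the spatial grid stays
  4× larger) and a single convolutional layer with 13 kernels + sigmoid
  produces one heat map per class; the class confidence is the maximum of
  its heat map. Dropout sits before the final convolution.

At the full 256 px input the FCN heat maps are 16×16; generally the output
side is `input_side / 2^(pool_blocks - 1)`. All weights use Glorot uniform
initialization. The compute engine behind these models (im2col convolution,
batch normalization, pooling, dense layers, and their exact gradients) is
implemented in the package's own Rcpp/RcppArmadillo code; gradients were
verified against central finite differences during development.

Parameters the protocol leaves open, with the package defaults:

| parameter | default | rationale |
|---|---|---|
| kernel size | 3 px | the stated initial filter size |
| base kernels | 16 at 256 px (8–16 at 64 px) | memory/width trade-off |
| dropout rate | 0.2 | middle of the searched grid {0.1, 0.2, 0.3, 0.5} |
| batch-norm placement | after the second conv of a block | sentence-order reading of the block description |
| FC widths | 128, 64, 13 | funnel to the 13-way output |

## FCN target masks

The FCN needs a binary spatial target although only image-level labels
exist. The green channel itself supplies it, in this fixed order:
min–max normalize → Gaussian smooth → threshold at 0.3 → binary dilate →
resize to the output grid. Choices the procedure description leaves open:

* *Normalization* is per-image min–max to [0, 1], which makes the 0.3
  threshold invariant to positive rescaling of the staining intensity.
* *Smoothing sigma* defaults to 2 px and the *dilation disc radius* to 3 px
  at 256×256, both scaled proportionally at other sizes. Smoothing and
  dilation run through EBImage (`filter2` with an explicit truncated
  normalized Gaussian kernel, circular boundary; `dilate` with an explicit
  disc `dx² + dy² ≤ r²`).
* *Resizing* is max-pool downsampling: an output cell is positive iff any
  input pixel in its receptive block is positive. Nearest-neighbour
  resizing would erase small bright structures such as a centrosome dot.
* A constant-zero channel yields an all-zero mask rather than a
  divide-by-zero; a constant positive image thresholds to its support.

The same mask is used as the target of every class present in the sample;
absent classes get all-zero targets. The whole pipeline is checked against
an independent per-pixel reimplementation in the test suite.

## Training protocol

Index-based splitting: the first `train_count` samples form the training
block, the last 10% of which is validation; the remainder is the test set
(at full scale 14,400 / 1,600 / 4,000 of 20,000). The loss is mean binary
cross-entropy over all sigmoid outputs. Optimization is Adam with learning
rate 0.001, beta1 0.9, beta2 0.999, epsilon 1e-8. The learning rate is
divided by 3 when the validation loss has not improved for 8 consecutive
epochs, and training stops early after 20 epochs without improvement; the
returned model carries the weights of the best-validation epoch.

Two readings of "did not decrease" are possible; the package compares each
epoch against the *running best* validation loss (standard plateau
semantics). The plateau counter resets after a drop so the rate is not
divided twice for one plateau, while the early-stopping counter keeps
accumulating across drops — hence the training state tracks the two
counters separately. Validation losses are computed in inference mode
(batch-norm running statistics), and epoch shuffling and dropout draw from
R's RNG, so a fixed seed reproduces a training run bit-for-bit on one CPU.

## Threshold calibration and evaluation

Sigmoid confidences are binarized with per-class thresholds selected on the
*training* predictions only: every grid value 0.00, 0.01, …, 1.00 is tried
and the dice coefficient `2TP / (2TP + FP + FN)` (identical to per-class
F1) is maximized; ties resolve to the smallest grid value, and a class is
called present when its confidence is `>=` its threshold. Dice with an
empty denominator is defined as 0 so that never-present, never-predicted
classes do not inflate averages. One consequence of the smallest-tie-break
rule worth knowing: a class entirely absent from the calibration split has
dice 0 at every threshold, so its calibrated threshold is 0.00 and it is
predicted everywhere; evaluations of deliberately restricted class subsets
should therefore intersect predictions with the trained classes.

The multi-label confusion matrix uses this attribution rule: a true class
that is found increments its diagonal cell; each missed true class gets one
hit from every predicted false positive. Rows are normalized by the number
of samples containing the row class, so the diagonal is per-class recall
and rows need not sum to one (a missed label with no false positives
contributes nothing off-diagonal). Classes absent from the evaluated truth
are dropped from unweighted means with a warning. Reported alongside:
unweighted mean of the normalized diagonal, unweighted mean dice,
correct-classification fractions stratified by the number of simultaneous
localizations (exact set match by default; an all-true-found variant is a
switch, since the stratified "correct %" definition is not pinned down),
row-conditional class co-occurrence fractions, and dice stratified by the
three most frequent cell-line tags plus a pooled "other" group.

## The synthetic simulator

The simulator emulates the data layout and statistical structure the
pipeline expects, not microscope physics. Each image contains 1–6
non-overlapping elliptical cells with strictly interior nuclei and a
cytoplasmic centrosome point. Three morphology tags stand in for cell-line
heterogeneity (medium round `lineA` 45%, large elongated `lineB` 45%, small
round `lineC` 10% — the minority tag mirrors the minority-cell-line
condition of the stratified evaluation). Each of the 13 classes has a
qualitative pattern renderer painted inside the cell geometry (filled
nucleus, nucleolar blobs, nuclear-membrane ring, cytosol fill, plasma-
membrane ring, vesicle dots, mitochondrial filaments, radial microtubules,
centrosome dot, juxtanuclear Golgi patch, perinuclear ER mesh, straight
actin fibers, wavy intermediate filaments). The green channel is the union
of the renderers of the present classes with ±20% per-cell intensity
jitter; blue/red/yellow carry the reference stains; additive Gaussian
background noise (sd 0.02) is clipped to [0, 1]. Every present class keeps
its exact binary ground-truth mask.

Label sets draw the number of simultaneous localizations from
(60.6%, 33.3%, 5.8%, 0.3%) — the observed multilocalization strata of
large cell-atlas data, with the 4-label entry rounded so the law sums
to one — then accumulate classes under a pairwise co-occurrence whitelist
(nucleoli with nucleus, vesicles with cytosol, …) so multi-label draws stay
spatially coherent. Marginal class weights default to a hand-set imbalanced
law (nucleus and cytosol dominant; actin filaments, ER and intermediate
filaments rare) echoing the imbalance such datasets show; the per-class bar
heights are not published as numbers, so these weights are the package's
own choice.

What the simulator does *not* reproduce: textured chromatin, antibody
chemistry, optical blur and shot noise, z-sectioning, touching cells,
annotation noise. Passing tests therefore demonstrate that the pipeline's
machinery — architectures, targets, optimization, calibration, metrics —
functions end to end, not that the model reaches any particular accuracy
on real microscopy data.

## Scaled-down end-to-end conditions

The self-contained learning demonstration (used by the test suite and by
`scripts/acceptance.R`) runs on one CPU in a few minutes: 600 images at
64 px, six well-separated classes in balanced proportions (NU, CY, VE, MT,
PM, NI; uniform marginal weights), multilocalization law (0.62, 0.30, 0.08,
0) keeping multi-label samples under 40%, split 432/48/120, batch size 8,
at most 15 epochs. The CNN uses base width 16, FC widths 128/64/13 and
dropout 0.1; the FCN uses base width 16 and dropout 0.2. Under these
conditions both variants reach class-average diagonal accuracy ≥ 0.80 on
the held-out split. Balanced class weights are deliberate here: with the
realistic imbalanced marginals a 600-image corpus leaves rare classes only
a few dozen training examples, which tests data volume rather than the
pipeline. The numbers printed by the acceptance script are descriptive
summaries of this scaled-down setting, not reproductions of full-scale
results, which would require the real corpus and GPU-scale training.

## Numerical notes and limitations

* Binary cross-entropy clips predictions to [1e-7, 1 - 1e-7]; the loss
  gradient is fused with the final sigmoid for numerical stability.
* The threshold grid is generated as `seq(0, 1, by = 0.01)`; comparisons
  use `>=` on the represented doubles.
* Batch normalization uses biased batch variance and running statistics
  with momentum 0.9.
* Max pooling breaks ties toward the first element in scan order;
  `which.max` ties in calibration resolve to the smallest grid value.
* Nearest-neighbour resizing maps output pixel centers back to input
  pixels, matching the stated resampling of the original captures.
* Training is single-threaded and deterministic given a seed; there is no
  GPU path, so full-scale (20,000 × 256 px) training is out of reach — the
  package targets method correctness and scaled-down studies.
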