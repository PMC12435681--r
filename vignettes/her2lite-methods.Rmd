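---
title: "Lightweight HER2 scoring networks: models, training and explainability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lightweight HER2 scoring networks: models, training and explainability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(her2lite)
```

## The problem

HER2 (human epidermal growth factor receptor 2) status determines whether a
breast-cancer patient receives targeted therapy. The clinical reference is
immunohistochemistry (IHC): hematoxylin stains nuclei blue and DAB deposits a
brown ring on the membrane of HER2-expressing cells, graded 0 / 1+ / 2+ / 3+
by staining intensity, membrane completeness, and the fraction of positive
cells. Routine H&E slides carry no visible HER2 marker, so scoring them
requires a model that picks up subtle morphology. `her2lite` implements two
deliberately small convolutional classifiers for this task — small enough for
CPU or edge deployment — together with the training protocols, label
groupings, metrics, and Grad-CAM explainability needed to study them end to
end.

Because the public histopathology corpora this problem is usually studied on
are large external downloads, the package ships a synthetic patch generator
that emulates the relevant generative factors at desk scale. Every empirical
claim the test suite makes is made on that generator, with the limitations
spelled out below.

## The two architectures

### ATHER2

`ather2()` builds a two-branch network. A shared stem (3x3/16 convolution,
2x2/2 max pool) feeds:

* a **left branch** of 3x3 convolutions with stride 3, each pool/dropout
  separated, whose first convolution is refined by a convolutional block
  attention module (CBAM); and
* a **right branch** mixing 3x3 and 5x5 convolutions with batch
  normalization, capturing broader patterns.

Each branch ends in global average pooling (128 features), the branches are
concatenated (256), and a 128-unit dense layer feeds the head — one sigmoid
unit for binary tasks, `K` softmax units otherwise. Hidden activations are
leaky ReLU (negative slope 0.3); conv/dense kernels carry an L2 penalty
(1e-4) during training. Both constants are configurable; the architecture
source only fixes the layer table, so these are the framework-conventional
defaults.

Two shape rules reproduce the published per-layer output sizes exactly and
are exposed directly: convolutions use *same* padding
(`conv_output_size(n, k, s) = ceiling(n/s)`), pooling uses *valid* padding
(`pool_output_size(n, k, s) = floor((n-k)/s)+1`). This is the unique padding
pair consistent with the whole layer table (256 -> 86 under a stride-3
convolution forces same/ceiling; 256 -> 254 under a stride-1 pool forces
valid). The left branch's valid pools impose a minimum input of 86x86;
`ather2()` reports the first failing layer for smaller inputs. The model
counts about 345.6k parameters; `summary()` gives the per-layer breakdown.

```{r}
m <- ather2(c(512, 512, 3), num_classes = 2)
count_parameters(m)
head(shape_trace(m), 6)
```

### CBAM

The attention block follows the canonical two-stage design: channel attention
(a shared two-layer MLP with reduction ratio 16 applied to the spatially
average- and max-pooled channel descriptors, summed, sigmoid) then spatial
attention (a 7x7 convolution over the stacked channel-wise mean/max maps,
sigmoid). Order matters — channel first, then spatial — and the test suite
pins that order. Both hyperparameters are configurable through
`cbam_config()`; the defaults are the canonical ones, since the architecture
source names the module without internals. With this reference configuration
the CBAM block adds 679 parameters on the 64-channel branch.

### PrunEff: block pruning of EfficientNetV2B0

`build_effnetv2b0()` constructs the full backbone (stem, fused-MBConv stages
1-3, MBConv stages 4-6 with squeeze-excitation, 1x1/1280 top) under the
canonical layer-naming scheme, so the five published stop layers resolve by
name. *Block pruning* (`prune_backbone()`) truncates at a stop layer and
`attach_projection_head()` appends a 7x7/192 same-padded convolution, batch
normalization, leaky ReLU, global average pooling and a dense head. The five
subnetworks SBN1..SBN5 are nested prefixes with strictly increasing
parameter totals; SBN4 (cut at `block4c_add`, 96 channels) is the PrunEff4
configuration. The projection conv's composition (BN + activation after it,
single dense output) is the package's choice where the source is silent; the
source's printed per-subnetwork totals imply additional unlisted head layers
and are not reconstructable, so only ordering and rounded-magnitude
contracts are enforced.

ImageNet checkpoints are external binary artifacts and are not bundled;
`build_pruneff(weights = ...)` loads any checkpoint saved with
`save_weights()`, and pruning preserves retained weights bit-exactly —
the property that matters for transfer.

## The CNN runtime

No deep-learning framework is assumed: the package carries its own runtime —
C++ (RcppArmadillo) im2col convolution, depthwise convolution and max-pooling
kernels under an R computation graph with reverse-mode differentiation, Adam,
batch normalization, dropout and the CBAM composite. Every layer's gradients
are validated against central finite differences in the test suite. Weight
initialization is fan-in variance scaling, fully determined by a seed;
forward passes in inference mode are deterministic.

One numerical choice deserves a note: with desk-scale cohorts an epoch
contains only a few minibatches, so the usual slow exponential moving average
for batch-norm inference statistics lags the weights badly. The trainer
instead keeps the running average of the current epoch's batch statistics
(momentum $(i-1)/i$ for batch $i$), which adapts immediately and is exactly
reproducible. At large batch counts this converges to the conventional
estimate.

## Training protocol

`train_config()` mirrors the studied protocol: Adam, cross-entropy, batch
size 24, at most 80 epochs, flip/shift augmentation, a plateau scheduler that
multiplies the learning rate by 0.1 when validation accuracy stalls, and
early stopping with restoration of the best-validation weights. The initial
learning rate comes from the grid {6e-2, 6e-3, 6e-4} — larger for fresh
networks, smaller for fine-tuning. At desk scale (tens of images per batch
epoch) Adam at 6e-2 is unstable, so the package's desk experiments use 6e-3
for fresh networks and 6e-4 for fine-tuning, both members of the stated
grid. Plateau patience is 5 epochs and early-stop patience 10 (the source
states the mechanisms, not the patience values); validation defaults to a
10% stratified, patient-grouped holdout. Early stopping restores best (not
last) weights.

Two pretraining workflows are provided. Generic transfer loads an external
checkpoint into the backbone. Domain-specific pretraining
(`domain_pretrain_finetune()`) trains the same architecture on a related
histopathology source task, transplants every feature weight bit-exactly,
re-initializes only the classification head at the target arity, optionally
freezes the first `n` weighted layers (counted in topological order from the
input; the CBAM block counts as one weighted layer), and fine-tunes. The
interpretation of "first n weighted layers" is the package's, since the
source does not enumerate the frozen layers.

## Synthetic cohorts: what they do and do not show

`generate_cohort()` renders class-conditional patches with per-patient style:

* **IHC**: blue elliptical nuclei on a pale background; a score-dependent
  fraction of cells carries a brown membrane ring whose DAB intensity and arc
  completeness grow with score — the three ASCO/CAP factors. Default
  profiles: score 0 (fraction 0.02, intensity 0.05, completeness 0.1),
  1+ (0.3, 0.3, 0.4), 2+ (0.5, 0.5, 0.9), 3+ (0.7, 0.9, 1.0). Ring pixels
  form the ground-truth mask.
* **H&E**: purple nuclei and pink cytoplasm with no brown channel; class
  signal is carried only by mild nucleus density/size trends — deliberately
  subtle, so the benefit of domain pretraining is observable on the stain
  where the real studies found it largest.
* **Patient style**: one small hue rotation (sd 0.10 rad about the gray
  axis) and brightness offset (sd 0.05) drawn per patient. This induces the
  optimistic gap between random patch-wise splits (`split_random()`) and
  subject-wise splits (`split_subjectwise()`).
* `generate_tumor_cohort()` provides a benign/malignant H&E source task with
  a strong morphological gap, emulating a routine tumour-detection corpus
  for pretraining.

These cohorts reproduce *directions*, not clinical numbers: passing tests
show the architecture can extract the encoded factors, that identity leakage
inflates random-split scores, and that feature transfer helps on subtle
tasks. They say nothing about stain variability, scanner effects, tissue
heterogeneity or real inter-observer noise.

## Metrics and label schemes

`group_labels()` implements the three groupings (4-class identity; 3-class
negative 0/1+, borderline 2+, positive 3+; binary negative vs positive with
2+ excluded). `confusion_and_summary()` reports the confusion matrix,
accuracy, macro-averaged precision/recall/F1 (macro is the conservative
choice where the source does not state the average; per-class values are
also reported), rank-based AUC (macro one-vs-rest beyond two classes), and
the multiclass Matthews correlation coefficient in covariance form with the
zero-denominator-gives-0 convention. The binary decision threshold is fixed
at 0.5. All metrics are cross-checked against brute-force oracles to 1e-12.

## Grad-CAM

`gradcam()` backpropagates the class score (the pre-sigmoid logit for binary
heads — signed for the negative class — and the class logit for softmax
heads, avoiding saturation) to any convolutional layer, weights each
activation map by the spatial mean of its gradient, rectifies the weighted
sum, and bilinearly upsamples with min-max normalization.
`localization_score()` quantifies agreement with the generator's membrane
masks as mass-inside-mask and its enrichment over the mask's area fraction.
On trained synthetic models the attention-refined L-1 layer concentrates on
membrane rings (median enrichment above 2); the colormap and blending of
`overlay_heatmap()` are deterministic but not pinned to any external
rendering.

## Problem sizes used by the test suite

The suite exercises full training runs at sizes a laptop CPU handles
comfortably, chosen once as the package's desk-scale study conditions:

* learnability: 12-patient, 8-patches-per-patient IHC cohort at 128x128,
  binary scheme, subject-wise 1/3 test split;
* pretraining direction: 12-patient H&E cohorts at 96x96 (a resolution from
  the published sweep), three seeds, benign/malignant source task;
* split-leakage direction: 12-patient IHC cohorts at 96x96, 3-class scheme,
  random vs subject-wise splits over three seeds;
* Grad-CAM enrichment: 20 strongly-positive patches against the learnability
  model.

## Known limitations

* The runtime is single-threaded and CPU-only; it is a study instrument, not
  a production inference engine.
* Published per-subnetwork parameter totals for the pruned family are not
  reconstructable from the stated composition; only ordering and rounded
  contracts are enforced (the full network's printed non-trainable count
  likewise exceeds the batch-norm moving statistics by 2).
* Synthetic cohorts are stylized; no claim about real-slide accuracy is made
  or tested.
* ImageNet weights are not bundled; generic transfer requires a
  user-supplied checkpoint.
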