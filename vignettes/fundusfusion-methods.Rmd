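---
title: "Methods: fluorescence-simulation preprocessing and dual-backbone fusion for multi-disease fundus classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluorescence-simulation preprocessing and dual-backbone fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Diabetic retinopathy, hypertensive retinopathy, glaucoma and media-opacity
("contrast"/cataract-type) disease all leave visible traces on color fundus
photographs: microaneurysms and hard exudates, arteriolar narrowing and
cotton-wool spots, an enlarged optic cup, or a global haze. `fundusfusion`
implements a complete, desk-scale pipeline for five-class fundus
classification (the four disease classes plus normal): deterministic
image enhancement, training-set augmentation and balancing, frozen
convolutional feature extraction from two backbone families, a trainable
fusion head, a gradient-boosted-tree head on deep features, Grad-CAM
saliency, and multiclass evaluation. A seeded synthetic fundus generator
makes every stage testable without any clinical data.

## Fluorescence-simulation preprocessing

The enhancement transform is pure channel arithmetic, chosen for
reproducibility rather than optical fidelity: the image is split into R, G,
B; the green channel — where fundus lesion contrast concentrates — is scaled
by a factor `alpha` (default 2.0), rounded half away from zero and clipped
at 255; the channels are re-merged as (R, G', B); optionally the blue
channel is zeroed (default on) so the amplified green reads as
fluorescence; and optionally the processed green channel is rendered
through a fixed 256-entry HOT lookup table (black to red to yellow to
white).

Numerical decisions worth stating explicitly:

* **Clipping** to 255 after rounding keeps the 8-bit image contract; the
  transform's definition alone does not bound `alpha * G`.
* **Rounding** is half-away-from-zero, computed in floating point, which is
  stable across platforms.
* The **HOT table** is defined arithmetically in the package (`R = clip(3t)`,
  `G = clip(3t - 1)`, `B = clip(3t - 2)` for `t = i/255`), so colormapped
  output is bit-exact everywhere and does not depend on any plotting
  library's palette.
* Step order follows the transform's tabulated definition: colormap, when
  requested, is applied after blue suppression. The classification path
  uses no colormap; it is a visualization branch.
* Whether blue suppression was active in the original experiments is not
  derivable from the source; it is exposed as a flag, default on.

With `alpha = 1`, suppression off and no colormap, the transform is the
identity — a property the test suite pins.

Note one consequence that shaped the synthetic data design below: with
`alpha = 2`, any source green above 127 saturates, so bright structures
(optic disc, cup, pale lesions) lose their green contrast and the red
channel carries most of the remaining distinction between pale lesion
types.

## Synthetic fundus generator

The generator renders parametric retinas: a circular field with a warm
base color and radial shading, an optic disc with a central cup, a
random-walk vessel tree rooted at the disc, and additive Gaussian pixel
noise (sd 3 on the 8-bit scale). Class signatures:

* **diabetic retinopathy** — dark-red dot hemorrhages (clusters of small
  disks) plus bright yellow exudate blobs;
* **hypertensive retinopathy** — vessels thinned to 0.45 of normal width
  plus soft, whitish-green cotton-wool patches;
* **glaucoma** — cup/disc area ratio drawn uniformly in 0.65–0.80 (normal
  eyes use 0.30), plus a pale peripapillary-atrophy ring around the disc.
  The ring is part of the signature because cupping alone is expressed in
  exactly the bright colors that the fluorescence transform saturates;
  peripapillary atrophy is a standard accompaniment of glaucomatous
  cupping and keeps the class detectable after enhancement;
* **contrast** — global haze (blend weight 0.45 toward mid-gray) plus an
  optical blur (Gaussian, sigma 0.008 of the short image side). The blur
  matters: haze alone is an affine intensity map that per-image
  standardization removes exactly, whereas media opacity clinically blurs
  as well as washes out.

Defaults emulate the acquisition setting the pipeline was designed
around: raw frames of 1125 x 1264 (width x height), resized to 700 x 600
for modelling; 100 images per class; stratified 15% held-out split. The
drawn cup/disc ratio and radii are recorded in image metadata so tests can
check the generator's self-report against the drawn shape areas.

What the generator does **not** emulate: real lesion texture,
illumination falloff from optics, camera vignetting, inter-eye anatomical
variation, label noise, or correlated acquisition artifacts. Passing
tests therefore demonstrate that the pipeline's machinery is correct and
that it can learn conspicuous, consistently rendered class structure —
not that it reaches any particular accuracy on clinical images.

## Augmentation and balancing

The augmentation policy language mirrors AutoAugment: ordered
sub-policies of (operation, probability, magnitude-level 0–9) over a
fixed vocabulary (rotate, translate, shear, flip, brightness, contrast,
color, sharpness, cutout, crop-resize). The learned policy of the
original AutoAugment work is not reproducible from the source, so the
default is a fixed, documented five-sub-policy table: rotation up to 15
degrees, translation up to 10%, shear up to 8 degrees, brightness and
contrast within 20%, cutout up to 10% of the area — plus a horizontal
flip base operation. Geometric fills are black, matching the black
border of fundus fields.

Balancing oversamples minority training classes with augmented copies
until all classes match the largest one. Originals are never deleted,
and the test split is returned bit-identical: augmentation applies to
the training data only.

## Frozen backbones and pooled features

Two feature extractor families are provided, each built from its
characteristic block: inverted residuals with linear bottlenecks and
ReLU6 (MobileNetV2 style), and MBConv blocks with squeeze-and-excitation
gating and swish (EfficientNetB0 style). The package treats backbones as
pluggable providers and ships self-contained `tiny` variants — a stem plus
three block stages, ending at 48 and 56 channels respectively — so the
test suite needs no downloads and a 32-image forward pass stays under a
second on one CPU. The `full` scale builds each family's deeper stack,
but since no pretrained weight zoo is bundled and no download source is
configured, it warns explicitly and initializes randomly from the seed.
Backbones are frozen by construction: nothing in the training path
touches their parameters, and checksums make that testable.

"Final convolutional layer" means the output of the last convolutional
stage before any classifier pooling, for both families; those maps are
also the Grad-CAM target. Global average pooling collapses each channel
to its spatial mean.

Input normalization defaults to per-image, per-channel z-scoring.
The alternative (scaling to [0, 1]) is available, but z-scoring removes
global illumination and color-balance variation — with randomly
initialized frozen extractors, that nuisance otherwise dominates the
pooled features and swamps lesion-level signal. This is also why the
contrast class carries a blur component (see above).

## Fusion head

Pooled features from the two backbones are combined by concatenation
(default). Element-wise sum and product are supported behind a trainable
linear feature-transform layer that first maps both inputs to a common
width; concatenation is the default because the pipeline's defining
equations specify it, while sum and product appear in the surrounding
prose as alternatives.

Two head variants:

* **basic** — Dense(128, ReLU) then Dense(K, softmax). Its parameter
  count has the closed form `(c_a + c_b + 1) * 128 + 129 * K`, which the
  tests check exactly.
* **extended** — three dense blocks, then Dense(850, ReLU), then the
  softmax layer. Each block applies a depthwise (per-channel) affine
  transform, max pooling, ReLU, batch normalization, and an additive
  in-block skip. Because the fused input is a vector (a 1 x 1 spatial
  grid), the depthwise convolution degenerates to a per-channel scaling
  and max pooling to the identity — the stated components remain
  well-defined without inventing spatial structure. The 850-unit layer
  replaces the 128-unit layer in this variant (the source is ambiguous on
  whether it replaces or follows it; replacing keeps a single penultimate
  layer).

Batch normalization follows the standard mini-batch formulation:
population mean and variance over the batch, `epsilon = 1e-5`, learned
per-feature scale `gamma` and shift `beta`, running statistics (momentum
0.1) for inference. Training-mode batches must contain at least two
samples.

Training minimizes categorical cross-entropy with Adam (learning rate
1e-3, batch size 32) over head parameters only, for a default of 15
epochs — the printed sources disagree on the epoch count (10 in the
algorithm table, 100 in the results narrative), so neither is privileged
and the default is a desk-scale choice. A stratified 10% validation split
is carved from the training data (the source shows validation curves but
states no fraction). Pooled features are standardized to zero mean and
unit variance using training-set statistics stored inside the model; this
is applied transparently at prediction time and differentiated through by
Grad-CAM.

## Gradient-boosted-tree head

The boosted head is an authored, transparent implementation: multiclass
softmax cross-entropy, per-sample gradients `g = p - onehot(y)` and
Hessians `h = p(1 - p)`, one depth-limited regression tree per class per
round, exact greedy split search maximizing
`0.5 (G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda) - G^2/(H+lambda))`, leaf
weights `-G/(H+lambda)`, shrinkage `eta`. Defaults: `eta = 0.3`,
`lambda = 1`, 50 rounds, depth 3 — standard boosting conventions, since
the source prints none. Base scores are log class priors, so an empty
ensemble predicts the training distribution. No histogram approximation
or column subsampling: exact greedy suffices at desk scale. An
established boosting library is used in the test suite only, as an
independent cross-check of predicted labels on a toy problem.

The head's input representation is configurable: penultimate activations
of the trained fusion head (default — the richer signal) or its softmax
probabilities; the source motivates both. A "depthwise feature
transform" option applies one depthwise convolution to each backbone's
feature map before pooling; identity kernels reproduce the standard path
bit-for-bit, which is tested. The tabulated algorithm attaches that
depthwise step to the tree learner itself, which cannot literally modify
a tree; it is interpreted as this upstream feature-map transform, off by
default.

Whether final predictions should come from the boosted head alone or an
ensemble with the softmax head is not specified anywhere; both heads are
exposed, both are evaluated, and the boosted head is the default primary.

## Grad-CAM

Because the head consumes globally pooled features, the spatial mean of
the class-score gradient over a feature map equals the head's gradient
with respect to the pooled feature divided by the number of positions.
Channel weights are therefore computed analytically by backpropagating
one class logit through the head (inference-mode batch norm is a fixed
affine map); the class-activation map is the ReLU of the weighted channel
sum, min-max normalized, bilinearly upsampled to the input size, and
renormalized. Degenerate all-zero maps stay all-zero rather than dividing
by zero. Maps are available per backbone and as their average; the source
does not say which layer it visualized, so the final stage of each
backbone is used. Although the source describes Grad-CAM as a
"preprocessing" step, heatmaps here are a diagnostic output only — the
classification path never consumes them.

## Evaluation

Per-class one-vs-rest sensitivity (= recall), specificity, precision and
F1 from the confusion matrix; overall accuracy; macro (unweighted) and
micro averages. The source prints single sensitivity/specificity values
for a five-class task without stating the averaging, so macro is the
default and micro is available. Zero-denominator rates are reported as 0
with an explicit flag, keeping reports machine-readable. Recall is
reported separately even though it equals sensitivity, mirroring the
source's metric tables.

## Problem sizes and reproducibility

The test suite and the acceptance script run the full pipeline at desk
scale: 100 images per class generated at 282 x 316 raw pixels and resized
to 210 x 180 — the same 7:6 aspect as the full-size 700 x 600 setting —
with tiny backbones and 15 training epochs. These sizes are the package's
own choice of a desk-scale experiment; the full-geometry path
(1125 x 1264 raw, 700 x 600 resize) is exercised on a small batch. One
scaling interaction is worth knowing: lesions whose size is proportional
to the field (dot hemorrhages especially) approach single-pixel scale at
reduced resolution, so very small desk resolutions under-represent the
diabetic-retinopathy signature; 210 x 180 keeps all five signatures
expressed.

Every stochastic stage is seeded from the single pipeline seed (data
generation, splits, augmentation draws, weight initialization, batch
shuffling), and runs write a reproducibility record (config, seed,
package and R versions). Two runs with the same configuration and seed
produce identical reports, which the acceptance suite asserts.

## Known limitations

* Backbone weights are random at every scale unless the user supplies a
  checkpoint; the `full` scale is an architecture without its pretrained
  weights and warns accordingly.
* The synthetic classes are conspicuous by design; accuracy numbers on
  them say nothing quantitative about clinical data.
* The boosted head's exact greedy splitter is O(features x n log n) per
  node and is not meant for feature widths far beyond the desk scale.
* The printed corpus-composition table that ships with the package is
  internally inconsistent (one row's cells sum to 4911 against a printed
  total of 4101); it is reproduced verbatim and flagged, never repaired.
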