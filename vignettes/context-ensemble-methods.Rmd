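---
title: "Context-ensemble classification of breast masses: methods and design notes"
author: "massContext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-ensemble classification of breast masses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the idea

Discriminating benign from malignant masses on screening mammograms is hard:
both share similar texture, and single-crop CNN classifiers are brittle —
one unlucky crop, one adversarially placed patch of dense tissue, and the
decision flips. Classical ensembles buy robustness by training many models,
which is expensive for deep networks.

`massContext` implements the alternative this package is built around: keep
**one** backbone network and manufacture decision diversity from the **input**
side, by scoring several crops of the same mass that differ in how much
surrounding tissue (context) they include, then fusing those per-crop
decisions into one mass-level call. The ensemble is over *views*, not over
*models*.

## ROI extraction schemes

Two families of context-diverse regions of interest (ROIs) are supported,
both producing 224 × 224 crops (the input size of ImageNet-lineage CNNs).
Coordinates are 0-based, half-open, row-major; crops clamp to image bounds;
all resizes are bilinear with output dimensions rounded half-up.

**Scale-based (`MS1`/`MS2`/`MS3`)** — `expandBBox()` grows the mass bounding
box by a fixed percentage of each side on each edge (a "5:5" ratio is read
as 5% per edge), and each expanded crop is anisotropically resized to
224 × 224. The scheme families are `{5,10,15,20,25}`, `{10,20,30,40,50}`
and `{50,60,70,80,100}` percent. Crops are nested by construction, so the
diversity is mostly in scale.

**Translation-based (`MC1`/`MC2`)** — the bounding-box crop is first
isotropically rescaled so its *smaller* side is 256 pixels (no anisotropic
distortion of texture), then 224 × 224 windows are cut from the four corners
and the center, and each window is flipped horizontally. Together with the
whole rescaled crop resized to 224 × 224 this gives the 11-ROI `MC2` scheme
in the fixed order `full, TL, TR, BL, BR, C, TLf, TRf, BLf, BRf, Cf`.

Two conventions here were genuinely open and are this package's choices:
5 windows + 5 flips make 10, so the stated 11th ROI is taken to be the whole
rescaled crop placed first — the minimal addition consistent with the
scheme's description; and the 3-context `MC1` variant, never enumerated at
the source, is the symmetric subset `full, C, Cf`. The ROI order is part of
the contract: stacked fusion indexes features by position.

## Enhancement

Screen-film mammograms have poor soft-tissue contrast. `enhanceROI()`
applies, in order: global histogram equalization (256 bins over the ROI's
own range), unsharp masking `out = in + 0.8 · (in − gaussian(in, σ = 1))`
clipped to the input range, and a 3 × 3 median filter. Strength 0.8 is the
prescribed value; σ = 1 is a conventional default and is exposed in
`enhancementConfig()`. Whether enhancement precedes or follows the resize to
224 × 224 is unstated at the source; this package applies it to the final
resized ROI so the kernel scale is uniform across ROIs, and the config makes
the stage skippable entirely (the correct setting for well-contrasted
full-field digital images, where enhancement is disabled and `enhanceROI()`
is a bit-identical identity).

## Training augmentation

`buildTrainingSet()` unions three families: sliding-window context crops (a
fixed window, by default the mass's longer side + 20 px, slides at a 10 px
stride over every offset where it contains the whole mass and stays inside
the image), orientation variants (clockwise rotations 0°/90°/180°/270°,
each optionally flipped — lossless array permutations on square crops), and
scale expansions (5% and 10% per edge). Whether the families compose or
union is unstated at the source; orientations are applied to the window
crops and scale crops are added separately, which matches how the three
families are illustrated, and the counts follow the closed form
`(⌊Δr/stride⌋+1)·(⌊Δc/stride⌋+1) · 8 + |scales|` per region.

## Backbone networks

The backbone is a declarative computational graph (`ArchSpec`) executed by a
compact CNN engine written for this package (im2col convolution lowered to
BLAS matrix products via RcppArmadillo, frozen-statistics batch
normalization, ReLU, max pooling, global average/max pooling, concatenation,
residual addition, a 2-way fully connected classifier and softmax, with
reverse-mode gradients and SGD-momentum training).

* **`base`** — the standard 5-stage bottleneck ResNet-50 (stage widths 64,
  256, 512, 1024, 2048) with the 1000-way classifier replaced by a 2-neuron
  layer.
* **`DI`–`DIV`** — four density-specific modifications that all operate on
  the last bottleneck block of the final 7 × 7 stage and fuse local and
  global features so that the concatenated feature entering the classifier
  is exactly **2048** channels, the unmodified width:
  * `DI`: the block's final 1 × 1 conv (2048 filters), its ReLU and its
    shortcut are removed, leaving a 512-channel map; GAP ∥ GMP over it
    (512 + 512) plus a projection shortcut from the first block of the
    stage (1 × 1 conv, 1024 filters, global 7 × 7 max-pool) = 2048.
  * `DII`: final conv replaced by 1024 filters, shortcut removed;
    GAP (1024) ∥ projection block (1 × 1 conv 1024 + 7 × 7 max-pool) = 2048.
  * `DIII`: final conv replaced by 512 filters, shortcut removed; GAP ∥ GMP
    (512 + 512) plus a projection from the last 14 × 14-stage block
    (1 × 1 conv 1024 + 14 × 14 max-pool) = 2048.
  * `DIV`: final conv replaced by 1024 filters, shortcut removed; GAP ∥ GMP
    after the block ReLU (1024 + 1024) = 2048.
* **`tiny`** — a reduced-depth three-stage backbone (16/32/64 filters) with
  the same GAP ∥ GMP head idea and a 128-wide feature, used for desk-scale
  experiments where a 23M-parameter network cannot be trained in minutes.

The projection max-pool kernels (7 × 7, 14 × 14) equal the spatial maps they
act on, i.e. they are global per-channel reductions. The source's block
notation is internally inconsistent in places; the channel arithmetic
(everything must sum to 2048) is the disambiguator, and both graph
inspection and forward-shape probing assert that contract for every variant.
A deliberate consequence of the surgery worth stating: only `DIV` has fewer
parameters than `base` — the 1 × 1 projection convolutions that `DI`–`DIII`
add outweigh the removed 2048-filter block (e.g. `DI` adds a 2048→1024
projection, 2.1M weights, while removing a 512→2048 conv, 1.0M).

No pretrained ImageNet weights are bundled (none are available offline);
`buildBackbone()` initializes He-normal random weights, which is sufficient
for shape/contract verification and for from-scratch training of `tiny`.
Grayscale input is replicated across 3 channels for the ImageNet-shaped
variants; `tiny` is single-channel.

**Training.** `fineTune()` uses SGD with momentum 0.9 and a 90:10 stratified
train/validation split, returning the best-validation-loss checkpoint with
early stopping (patience 5). The default learning rate 1e-4 is the
fine-tuning rate appropriate to pretrained weights; from-scratch desk-scale
runs in this package use 0.015 (batch 32, 8 epochs), chosen once as a
conventional from-scratch setting for a small network. Batch-norm layers run
on frozen statistics during fine-tuning — the common choice when the
original statistics cannot be re-estimated from small batches.

## Fusion

Per-ROI probability pairs `(p_benign, p_malignant)` are fused by:

* **majority vote** over per-ROI argmax labels;
* **soft vote**: per-class means, then argmax;
* **max vote**: per-class maxima, then argmax;
* **stacking**: the ordered vector of per-ROI malignant probabilities
  (length 11 for `MC2`; one probability per ROI — the benign one is
  redundant since pairs sum to 1) is standardized and passed to an SVM
  (RBF/linear/polynomial kernel) or random forest meta-classifier, trained
  on backbone predictions over the training and validation regions.

All ties resolve to *malignant*: screening prioritizes sensitivity, and the
benign branch requires a strictly larger benign probability. SVM
hyperparameters are unstated at the source; the defaults are `C = 1`, RBF
`gamma = 1/n·var` (e1071's default on standardized features), polynomial
degree 3, all exposed in `fitStacker()`. Raw softmax outputs are used
without recalibration.

## Metrics

With malignant as the positive class: sensitivity TP/(TP+FN), specificity
TN/(TN+FP), accuracy, Cohen's kappa `(Po − Pe)/(1 − Pe)` with `Po` the
observed and `Pe` the chance agreement, F1, and rank-based (trapezoidal,
midrank-tied) ROC AUC. Percentages are rounded half-up to 2 decimals for
reporting; metrics with zero denominators are `NA`, never 0. The F1
tabulated at the source matches the standard precision/recall harmonic mean
rather than the sensitivity/specificity formula its text prints;
`computeMetrics()` implements precision/recall as primary and exposes the
other definition behind `f1Definition = "sen-spe"`.

`reconstructConfusion()` inverts printed sensitivity/specificity and class
counts back to the unique integer confusion matrix they round to, which lets
published result rows be audited for internal consistency — the package's
acceptance tests reproduce the published CBIS-DDSM rows this way (the
CBIS-DDSM test split has 182 benign and 132 malignant masses).

## Synthetic fixtures

`generateDataset()` builds phantoms: a Gaussian-smoothed noise background
whose texture amplitude grows with the BI-RADS density tag, plus one bright
lesion — benign: a smooth ellipse (semi-axes 35–65 px) with a ~2 px sharp
margin; malignant: a star-convex blob (8–14 spicules, mean radius 35–55 px)
with a Gaussian-blurred (σ = 3) margin. Noise SD is 0.02 on the unit scale;
images are 512 × 512 8-bit by default (16-bit mode exists for the TIFF
path). The classes are separable by margin sharpness and spiculation — the
same visual axes that distinguish real benign and malignant masses — which
is exactly what the pipeline must learn to exploit; a three-feature summary
(margin gradient, eccentricity, boundary complexity) linearly separates them,
and the test suite asserts it.

What the phantoms deliberately do **not** model: real parenchymal texture,
pectoral muscle, calcifications, overlapping glandular structures, scanner
characteristics. Passing the end-to-end test therefore demonstrates that the
pipeline is wired correctly and can learn a margin/spiculation axis — not
that it reaches any particular clinical accuracy.

## Problem sizes and numerical choices

The end-to-end check trains `tiny` on the `MC2` ROIs of 140 training
regions (100 phantoms per class, 70:30 split), fits the RBF stacker, and
evaluates the 60 held-out regions — about two and a half minutes on one
CPU, reaching ≥ 90% test accuracy with the stacked decision at least as
good as the single-ROI one. Forward probing of the five full variants uses
random weights (a few seconds per variant). Degenerate inputs are defined,
not patched around: a square crop yields coincident corner windows (still
11 ROIs), a constant image is a fixed point of enhancement, an expansion
that would clamp a side below 1 px raises an error, and empty ROI sets or
single-class training sets are rejected with informative errors.

## Known limitations

* No DICOM reader: manifests reference PNG or 16-bit TIFF images.
* No pretrained weights, so the full ResNet-50 variants are
  contract-verified and trainable in principle but not trained to clinical
  accuracy here.
* The stacker's feature length is bound to the extraction scheme; bundles
  refuse mismatched vectors rather than adapting.
* Mass detection/segmentation is out of scope — a bounding box is required
  input.
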