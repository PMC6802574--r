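---
title: "Feature transfer for taxonomic image identification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature transfer for taxonomic image identification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepident)
```

## The model

`deepident` treats identification as *feature transfer*: a convolutional
network trained on a large generic image task is used, frozen, as a feature
extractor, and only a linear classifier is trained on the target data. The
assumption is that the convolutional blocks of such a network compute
general-purpose visual descriptors — edges and colours early, textures and
part-like patterns later — that remain informative for fine-grained
taxonomic categories the network never saw. This is the right regime for
collections data: tens to a few hundred images per category are far too few
to train a deep network, but plenty for a linear max-margin classifier in a
fixed feature space.

The backbone follows the VGG16 convolutional layout: five blocks of 3×3
convolutions with ReLU, each ending in a 2×2 max-pool that halves the
spatial extent, with filter depths 64, 128, 256, 512, 512 (blocks c1–c5).
For an S×S input, block ck emits an (S/2ᵏ)×(S/2ᵏ)×Fₖ activation volume, its
*feature matrix*; c5's output is the conventional "bottleneck" tap. The
fully connected head is never used.

Three feature-construction choices are exposed because they matter
empirically:

* **Pooling operator** — global average or global max over each filter's
  spatial slice. Average pooling is the default: on textured specimen
  images it summarises the whole object rather than a single strongest
  response, and it was the more accurate operator in our fixture ablations.
* **Intermediate pooling level N** — between global pooling (1×1×F) and the
  full flattened matrix there is a family of N×N×F summaries that keep
  coarse spatial layout. All of c3/c4/c5 are first standardised to the
  reference side S/16 (c3 is average-pooled 2×2 stride 2; c4 is already
  there; c5 is tapped *before* its final max pool), zero-padded by one pixel
  per side, pooled to N×N, and flattened in a fixed order (spatial
  row-major, filter fastest). At S = 416 the reference side is 26, padding
  gives 28, and the admissible levels are N ∈ {2, 4, 7, 14, 28}; N = 1
  means plain global pooling of the unpadded matrix — the padding exists
  only to make the window arithmetic exact and never enters the N = 1
  average.
* **Fusion and normalisation** — feature vectors from several blocks may be
  concatenated (ascending block order), combining early colour/texture cues
  with later shape-like cues; signed square root normalisation
  sign(x)·√|x| is then applied once to the fused vector, compressing rare
  large activations that otherwise dominate a margin objective.
  l2 normalisation is implemented but off by default — in our setting, as
  in the experiments this design follows, it does not help.

The classifier is a linear one-vs-rest SVM: one weight vector and bias per
category, prediction by highest decision score, and top-k suggestion lists
ranked on the raw scores (the linear SVM provides no probabilities; exact
ties break by ascending category order so rankings are deterministic). The
binary subproblems are solved by the libsvm linear-kernel C-classifier
(e1071) with cost 1, tolerance 1e-4, and no feature scaling; the
one-vs-rest assembly re-orients each binary solution so the positive
category always scores higher. These are this package's documented
defaults, not claims about any other implementation's internals.

## Evaluation protocol

Accuracy is the proportion of held-out predictions that exactly match the
true label; error rate is its complement. Ten-fold stratified
cross-validation is the default: within each category the seeded, shuffled
records are dealt to folds in turn, so per-category counts differ by at
most one and any remainder lands in the lowest-indexed folds. Each fold is
the test set exactly once.

When a dataset contains several images of the same physical specimen,
image-level folds leak: the test set contains specimens seen in training,
inflating accuracy. `grouped_folds()` therefore assigns whole specimens to
folds (stratified at specimen granularity — specimen counts per category
are balanced; image counts then follow approximately, which is as much as
grouping allows), and an invariant checked on every run is that no
specimen ever spans a train/test boundary.

A training split can lack a rare category entirely (e.g. a category with
fewer images than folds). The report records the fold/category pair and the
fold is still evaluated; such categories simply cannot be predicted in that
fold.

t-SNE feature maps are produced by an exact O(n²) implementation
(perplexity calibrated per point by bisection, default perplexity 30,
early exaggeration ×12, momentum gradient descent, seeded random
initialisation). It is unsupervised — labels only colour the plot — and is
intended for dataset-scale visualisation, not for thousands of points.

## The synthetic fixture generator

The generator emulates the *structure* of specimen-image datasets, not
their biology: K categories, each a parametric motif (body hue, stripe
frequency, and the count and size of white spots — deliberately the kind of
cue that separates close species); synthetic specimens as motif instances
(a fixed spot layout) photographed 4–5 times with nuisance variation in
scale, position, rotation, background tone, noise, and stored image size
(non-square, to exercise aspect-preserving resizing). `easy` specs separate
categories by hue and gross motif; `hard` specs share one hue and differ
only in spot statistics, forcing fine-grained discrimination.

What passing fixture tests shows: the pipeline's mechanics — geometry,
determinism, fold hygiene, the direction of ablation effects — are correct,
and the feature path preserves enough signal for linear separation of
visually distinct classes. What it does not show: performance on real
photographs, which have backgrounds, damage, imaging variation and far
subtler category differences; real-data accuracy requires the pretrained
backbone and real images, both external downloads.

The study conditions pinned for integration tests and the acceptance script
are: easy — 4 categories × 12 images, 4 per specimen; hard — 4 categories ×
16 images; 64-pixel inputs (matching the 48–96-pixel fixture images and
keeping a CPU forward pass cheap); c4 global average + signed square root
for the single-block runs; 10-fold stratified CV. With these, the easy
end-to-end run reaches ≥ 95 % cross-validated accuracy, and on hard
fixtures average pooling beats max pooling and c3+c4+c5 fusion beats the
best single block — the same directions the method shows at full scale.

## Numerical and design choices

* **Random padding noise** is i.i.d. uniform over the 256 8-bit levels per
  pixel and channel, from a seeded generator: the least-informative filler,
  so padding amount cannot become a label cue. Centring with odd margins
  puts the extra pixel bottom/right. Resampling is bilinear; upscaling is
  allowed for sources smaller than S.
* **The fixture backbone** uses one convolution per block (the full layout
  uses 2–3) with He-scaled Gaussian weights: identical shape semantics at a
  fraction of the cost, and a pure function of its seed. The pretrained
  adapter applies the canonical input preprocessing of the published VGG16
  ImageNet weights (0–255 scale, BGR order, channel-mean subtraction)
  inside the adapter, keeping the preprocessing module backbone-agnostic.
* **Geometry beyond S = 416.** The intermediate scheme generalises by
  taking c4's post-pool side (S/16) as the reference, padding +1 per side,
  and admitting any N that divides the padded side. S = 416 reproduces the
  published 52→26→28 chain with N ∈ {2, 4, 7, 14, 28} exactly; other sizes
  change the admissible set (e.g. S = 224 gives reference 14, padded 16,
  N ∈ {2, 4, 8, 16}).
* **Bottleneck tap for global pooling** is c5 *post*-pool; the c5
  *pre*-pool tap is used only by the intermediate scheme. Both are exposed
  as `tap_points` in `extract_features()`.
* **Flatten order** (spatial row-major, filter fastest) is arbitrary but
  fixed: a linear classifier is invariant to any consistent permutation
  (tested), but caches, models and fused vectors must agree on one.
* **Zero vectors** pass through l2 normalisation unchanged; signed square
  root maps 0 to 0 and preserves signs elementwise.
* **Determinism.** Every stochastic component — padding, fixture weights,
  fixture rendering, subsampling, fold assignment, t-SNE initialisation —
  takes an explicit seed, runs in a private RNG scope, and never touches
  the caller's RNG state. Identical configs produce byte-identical
  reports.
* **Feature caching** stores per-image block feature matrices keyed by
  image path, geometry, resize settings, backbone identity, block and tap
  point, so the ablation grid re-runs pooling/fusion/classifier variants
  without repeating forward passes.

## Known limitations

* The pretrained path requires externally supplied VGG16 ImageNet weights
  converted to the documented RDS layout; without them the package's tested
  path is the fixture backbone, and no claim is made about real-data
  accuracy from fixture results.
* The forward pass is plain R (im2col + BLAS); fine at fixture scale and
  usable for moderate real datasets with caching, but not a GPU substitute.
* Specimen-grouped stratification balances specimens, not images; with
  very uneven images-per-specimen counts, fold sizes can drift.
* The exact t-SNE is quadratic in n.
* Hinge loss (libsvm) rather than squared hinge is used in the binary
  subproblems; at the margins involved here the fitted separators agree
  with the closed-form maximum-margin solutions to numerical tolerance
  (tested), but the two losses are not identical in general.
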