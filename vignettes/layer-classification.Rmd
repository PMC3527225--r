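---
title: "Localizing genes to cerebellar layers from ISH images: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing genes to cerebellar layers from ISH images: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In-situ hybridization (ISH) reveals where a gene's RNA is expressed in a
tissue slice. In the cerebellum, expression is often confined to one of
four laminae — the thin Purkinje layer, the dense granular layer, the
outer molecular layer, or the inner white matter — and knowing which genes
are layer-specific is a building block for dissecting cell-type-specific
transcription. Manual annotation does not scale to genome-wide image
collections, and registration-based comparison of expression volumes is
fragile here: brains differ in their detailed anatomy, and a shift of a
few microns is enough to misalign a stripe that is only a few cells wide.

`cereblayers` implements a registration-free alternative: represent each
image by statistics that are insensitive to where exactly the folded
cortical sheet sits in the frame, classify images with a kernel SVM, and
combine the several images available per gene into a single gene-level
decision.

## Image representation

Masked expression images encode intensity with a heat colormap
(black → red → yellow → white); `heat_to_intensity()` inverts it by
nearest-neighbor lookup against a 256-entry table, which tolerates small
color perturbations from lossy compression. Pure black (no detected
expression) maps to exactly 0, and completely black images are excluded
(`is_blank()`); grayscale inputs bypass the inverse map.

Each image is then analyzed at multiple scales. `downsample()` averages
`f × f` blocks (trailing partial blocks are dropped rather than padded,
which would bias texture statistics at the borders), and
`build_pyramid()` stacks the levels. Coarse levels see the gross folded
"finger" geometry of the cerebellar sheet; fine levels see the per-layer
texture made by the spatial arrangement of expressing cells. The default
factor set is {1, 2, 4, 8, 10, 16}; it is configurable, and a 256 px
image keeps usable LBP statistics even at factor 16 (a 16 × 16 level).

At every level the image is summarized by a histogram of local binary
patterns, LBP(8, 2): each interior pixel is compared with 8 points on a
circle of radius 2 (off-grid points bilinearly interpolated), a neighbor
`>=` the center sets its bit, and the 8 bits form a code in 0..255. The
histogram of codes plus the level's mean intensity give 257 features per
level; histograms are scaled to [0, 1] by their own maximum bin, and
level blocks are concatenated (6 levels → 1542 features). Uniform LBP
(merging high-transition codes) is deliberately not offered: the codes it
merges away carry exactly the irregular structure that distinguishes
expression textures.

Conventions that had to be fixed once: ties count as "neighbor ≥ center"
(so a constant image gives code 255 everywhere); bit 0 points east with
angles counter-clockwise (any fixed convention is equivalent up to a bin
permutation); zero-valued background pixels participate in codes and
histograms, because the background/foreground boundary is informative
structure; the mean-intensity feature is kept raw (it is already in
[0, 1]) rather than rescaled with the histogram block.

A note on invariance. LBP is prized for being unchanged by monotone
intensity transforms. With circular sampling this is exact at the four
axis-aligned neighbors (which sit on grid points), and exact for all
eight neighbors under strictly increasing *affine* maps — gain and offset
changes, which is the dominant staining variation across brains. For
general nonlinear monotone maps, bilinear interpolation does not commute
with the transform, so a code can flip when an interpolated value crosses
the center intensity; the test suite asserts the exact affine form of the
invariance.

## Classification

**Image level.** An RBF-kernel SVM (`train_image_classifier()`, backed by
libsvm via kernlab on precomputed kernel matrices) scores each image; the
signed distance from the separating hyperplane is the image's confidence
score. Class imbalance is absorbed by weighting misclassification costs
inversely to class frequency (`c+ : c- = n- : n+`). Because libsvm's
decision sign depends on internal label ordering, every fit stores an
explicit orientation determined from the training decisions.

Hyper-parameters `(C, γ)` are tuned by `grid_search_hyperparams()` over
log-spaced grids (`C ∈ 2^-3..2^7`, `γ ∈ 2^-9..2^6`). Two numerical
choices deserve explanation:

* *Why γ reaches 64:* max-scaled LBP histograms are sparse and
  concentrated, so typical squared distances between feature vectors are
  far below 1 (median ≈ 0.02 on the synthetic benchmark); kernels only
  start to discriminate once `γ·d²` is of order 1. Much larger γ values
  (≥ 2^9) produce near-identity kernels on which the SMO solver stalls,
  so the grid stops at 2^6.
* *Selection metric:* each grid point is scored by the AUC of its
  out-of-fold decision values pooled across the inner folds, not by the
  mean of fold-wise AUCs. On separable data many grid points tie at
  fold-wise AUC 1.0, and the tie-break (smaller C, then smaller γ, for
  stability) would then land on a degenerate corner whose decisions rank
  perfectly *within* each fold but drift in offset *between* refits.
  Since the gene-level classifier is trained on exactly such pooled
  out-of-fold scores, the pooled-AUC metric penalizes that instability at
  the moment of selection.

**Gene level.** A gene typically has 2–8 images from different slices and
brains, so the task is multiple-instance: the label belongs to the bag.
`pool_scores()` reduces the image scores to five statistics — mean,
median, and the top-3 order statistics (k = 3, configurable). Genes with
fewer than three images have their lowest score duplicated to fill the
missing top-k entries; mean and median stay on the original scores, since
the duplication rule exists to complete the order statistics (this choice
affects only 1–2-image genes and is deliberately kept visible here). A
linear SVM over the five pooled features (`train_gene_classifier()`)
makes the gene call; its C is tuned the same pooled-AUC way, and the same
inverse-frequency cost weighting is applied (the imbalance argument holds
at the gene level too).

Four strategies are exposed for comparison (`predict_gene()`,
`evaluate_strategies()`): the full `two_level` classifier; the
`mean_image_score` baseline (average pooling of scores); the
`mean_lbp_features` baseline (average the feature vectors per gene, then
classify once); and the `single_image` baseline, which scores every image
independently and evaluates at the image level.

## Evaluation protocol

All cross-validation is *gene-grouped*: folds are assigned to genes, so
no gene ever has images in both train and test — images of one gene are
near-duplicates, and splitting them would leak. `make_cv_plan()`
stratifies by label and balances fold sizes to within one gene.

`evaluate_strategies()` runs nested 5-fold CV per task. In each outer
fold, the inner grid search sees only training genes; the gene-level SVM
is trained on out-of-fold image scores of the training genes (an inner
5-fold pass with the tuned hyper-parameters), never on scores produced by
a model that saw the same images; the `mean_lbp_features` model reuses
the `(C, γ)` tuned for the image-level task in that fold — gene-averaged
features live on the same scale, and a second grid search would double
the cost for no observed benefit. Every split (outer, inner grid, inner
out-of-fold) is recorded and can be audited with `audit_no_leakage()`.

AUC is computed in the exact Mann–Whitney midrank form (half credit for
ties), which equals trapezoidal ROC integration; fold-wise AUCs give the
reported mean ± sample standard deviation (n − 1), and ROC curves pool
the out-of-fold scores across folds (fold-wise curves would need
arbitrary interpolation to average). `one_vs_one_confusion()` reports
`1 − AUC` for every class pair, and `resolution_ablation()` compares each
single downsampling factor against the concatenated multi-scale
representation on identical folds.

## The synthetic benchmark

The generator (`generate_dataset()`) exists so the whole pipeline can be
built and tested without any external image corpus. It emulates the
features the classifier exploits, not cerebellar anatomy: a sinusoidally
folded band skeleton with 2–4 "fingers" stands in for the folded cortical
sheet, and each class renders its signature relative to that skeleton —
a thin bright stripe (Purkinje), a wide dense-speckle band (granular),
the outer band *plus* the stripe (molecular, mirroring the fact that
molecular-layer genes are also expressed in the Purkinje layer), a patchy
interior core (white matter), and three non-localized negative
sub-patterns (diffuse field, random blobs, near-blank). Per-gene
parameters (fold count, amplitude, widths, expression level, speckle
density) are drawn from a gene seed; each image of a gene then applies
independent affine jitter and resamples its texture, emulating different
slices and brains. Jitter amplitudes are free parameters
(`jitter_defaults()`); nothing in the literature quantifies inter-brain
deformation, so the defaults were set once to produce clearly related but
visibly different images. Backgrounds are exactly zero, and intensity 0
is the degenerate blank limit used to exercise the blank filter.

What passing tests on this generator do and do not show: the synthetic
classes are separable by construction (the default benchmark saturates
near AUC 1.0, comfortably above the 0.90 the acceptance suite requires),
so green tests demonstrate that the machinery — features, pooling, nested
CV, leakage control — works end to end. They do not certify accuracy on
real ISH data, which has segmentation artifacts, partial slices, probe
background and label noise that the generator deliberately omits.

## Problem sizes and numerical choices

The standard benchmark uses 40 genes per layer plus 120 negatives
(≈ 1400 images at 256 px; ~280 genes total, echoing the scale of a
hand-curated labeled set), features at factors {1, 2, 4, 8, 10, 16}, and
nested 5-fold CV; the resolution-ablation study uses 20 genes per layer
plus 60 negatives and a 3-point C grid, which is ample for the
single-factor-vs-multi-scale comparison while keeping its 28 nested
evaluations cheap. Inner fold counts
cap automatically at the smallest class size. A grid with a single point
skips the search entirely. Degenerate inputs fail loudly: single-class
training sets, images smaller than the LBP border, pyramid levels smaller
than the downsampling factor, empty score lists, and AUC on one class all
raise errors rather than guessing.

## Known limitations

* Scores are uncalibrated margins; strategies are comparable by rank, not
  by absolute value, and no probability calibration is provided.
* The generator's classes are more separable than real ISH material;
  reported synthetic AUCs should be read as integration checks, not
  accuracy claims.
* General multi-instance losses (mi-SVM etc.) and attention pooling are
  out of scope; pooling is the fixed five-statistic summary.
* Exact LBP invariance under arbitrary monotone intensity maps holds only
  at the grid-aligned neighbors, as discussed above.
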