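---
title: "Texture analysis of corneal stroma decellularization: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture analysis of corneal stroma decellularization: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stromatex` quantifies the morphological consequences of corneal
decellularization in brightfield micrographs. Removing keratocytes and
partially homogenizing the collagen lamellae changes the *texture* of the
stroma long before the change is obvious to the eye: the gray-level field
becomes more uniform and locally homogeneous, and the high-frequency content
drops. The package measures this with two complementary descriptor families
computed per region of interest (ROI), compares them across treatment groups
nonparametrically, and trains classifiers on them. This vignette documents
the models, the tunable parameters, the synthetic data generator that stands
in for unavailable real micrographs, and the numerical design choices.

## The texture model

### Gray-level co-occurrence matrix

A ROI is first reduced to integer gray levels (default 8-bit, 256 levels;
`quantize_levels()` maps to fewer levels via the order-preserving floor map
`pixel %/% 2^(bit_depth - target_bits)` when a coarser quantization is
wanted). The co-occurrence matrix `p(i, j)` is the normalized count of pixel
pairs in which a pixel of level *i* has a pixel of level *j* at a fixed
displacement. Conventions, fixed once and recorded alongside every feature
row:

* **Offset** `(0, +1)`: the neighbour is horizontally adjacent on the right.
  Averaging over four directions is deliberately not the default — a single
  fixed direction keeps the statistic interpretable and matches common
  texture-analysis practice for histology; any offset can be passed to
  `compute_glcm()`.
* **Asymmetric accumulation**: only the `(i, j)` order is counted.
  `symmetric = TRUE` adds the reversed pair for comparison with toolkits
  that symmetrize by default.
* **Gray-level count**: feature magnitudes depend strongly on it (contrast
  scales with squared level differences, ASM shrinks with the number of
  occupied cells), so the bit depth travels with the features in every
  output table.

Five features are computed from `p(i, j)`: ASM (`glcm_asm()`), IDM
(`glcm_idm()`), contrast (`glcm_contrast()`), correlation
(`glcm_correlation()`), and sum variance (`glcm_sum_variance()`). Two of
them involve conventions worth stating explicitly:

* **Contrast** uses the classical second-moment weights,
  `CON = Σ (i−j)² p(i,j)` — weight exponent 2 on the level difference,
  probability to the first power.
* **Sum variance** is the variance of the gray-level-sum distribution
  `p_{x+y}(k) = Σ_{i+j=k} p(i,j)` about the *sum average*
  `SA = Σ k p_{x+y}(k)`. (The alternative classical variant centers on sum
  entropy; centering on the sum average keeps the feature a genuine
  variance, with `SVAR = 0` exactly when `p_{x+y}` is a point mass.)

**Degenerate ROIs.** On constant texture both marginals of the GLCM have
zero variance and correlation does not exist. `glcm_correlation()` raises a
typed `undefined_feature` error rather than silently returning NaN;
`compute_feature_table()` catches it, drops the ROI, and reports the dropped
count. Real micrographs essentially never trigger this; saturated or masked
frames do.

### Wavelet subband energies

`dwt2_level1()` performs one level of a separable two-dimensional discrete
wavelet transform with the orthonormal Haar pair
(`(a+b)/√2`, `(a−b)/√2`). Haar at level 1 was chosen because it is the
simplest energy-conserving analysis filter (the Parseval identity
`Σ LL² + Σ LH² + Σ HL² + Σ HH² = Σ pixel²` holds exactly for even
dimensions, and the test suite asserts it to 1e-9 relative), and because the
detail energies of smooth versus rough texture are what the analysis needs
— finer filter choices change magnitudes, not direction. The family argument
exists as a configuration point; only `"haar"` is implemented.

Subband naming follows a fixed convention, stored in the result: the first
letter is the filter applied along the horizontal (x) axis, the second along
the vertical (y) axis. So LH responds to horizontal banding (variation along
y), HL to vertical banding, HH to diagonal detail and fine speckle.

Energies are normalized by the number of pixels in the *ROI*, not by the
subband's own coefficient count: `En = Σ d² / n`. Odd-sized inputs are
extended by replicating the last row/column before filtering; the default
300-pixel ROI is even, so level 1 is exact there.

## The synthetic micrograph generator

Real decellularization micrograph sets are generally not publicly
deposited, so the generator exists to give the pipeline a data source whose
ground truth is known. It targets the *statistical signature* of stromal
texture, not visual realism:

| parameter | default | meaning |
|---|---|---|
| `size` | 512 px (300 px in the pipeline default, matching the ROI size) | frame side length |
| `fiber_wavelength` | 16 px | dominant lamellar band period |
| `fiber_orientation` | 0.35 rad | band orientation; mostly horizontal variation, so the default GLCM offset probes across the bands |
| `fiber_contrast` | 0.18 | banding amplitude on the [0, 1] gray scale |
| `nucleus_density` | 2 per 10⁴ px | expected keratocyte nuclei; at the default ellipse size nuclei cover under 2 % of the frame, consistent with keratocyte sparsity in stroma |
| `nucleus_axes` | (8, 3) px | semi-axes of the dark ellipses: flattened nuclei elongated along the fiber direction |
| `nucleus_darkness` | 0.45 | gray-level drop inside a nucleus (hematoxylin-dark) |
| `smoothing_sigma` | 1 px | optical blur |
| `noise_sd` | 0.04 | fine-grain tissue speckle |

Composition order: oriented sinusoid (amplitude-modulated by a seeded
low-pass noise field, so bands wax and wane), minus dark ellipses at
Poisson-distributed positions, plus Gaussian speckle, then the Gaussian
blur, then an affine map to 8-bit levels with clamping. **The speckle is
added before the blur**: it models sub-resolution tissue texture, part of
the specimen, which treatment-induced homogenization genuinely smooths. Were
the noise added after the blur, every severity grade would share an
identical high-frequency noise floor and the HH wavelet energy would no
longer distinguish intact from decellularized texture — an artifact of the
composition order, not of the biology being emulated.

Decellularization severity is modeled by `severity_grades()`: grade
multipliers (1, 0.1, 0.05, 0.02, 0) scale the nucleus density and extra blur
(0, 0.5, 0.75, 1, 1 px) is added, for `native` and `g1`–`g4`. The grades
emulate a dose/duration series from mild to complete cell removal; the
monotone decrease of nucleus counts and of contrast-type features along the
series is asserted by the tests.

**What the generator does not model** — and hence what passing tests do and
do not show about real data: lamellar *misalignment and damage* (a
morphological change scored by humans, not a texture parameter here);
staining variation between batches; epithelium, Bowman's membrane and
endothelium; uneven illumination; magnification/scale variation. Tests
passing on synthetic data demonstrate that the feature mathematics, the
statistics and the classifiers behave correctly and recover a known effect
direction; they do not certify classifier accuracy on any particular real
staining and imaging protocol. On this synthetic contrast the two default
classes are in fact fully separable, so classifier metrics saturate at 1.0
— real micrographs, with their additional nuisance variation, sit lower.

All generation is a pure function of `(params, grade, seed)`; per-image
seeds in `generate_micrograph_set()` derive deterministically from the
master seed, the grade index and the image index, so datasets are
bit-reproducible and any single image can be regenerated in isolation.

## Group statistics

Per-feature group comparison uses the Kruskal–Wallis omnibus test on
mid-ranks with the standard tie correction (ties are real: features of
quantized images can coincide), followed by Dunn's rank-based pairwise
z tests,

`z = (R̄_a − R̄_b) / sqrt((N(N+1)/12 − tie term) · (1/n_a + 1/n_b))`,

with two-sided normal p values and Bonferroni adjustment
`p_adj = min(1, m·p)`. The comparison set is explicit: `"all"` pairs or
`"versus-control"`, and the Bonferroni multiplier `m` follows the chosen
set. Degenerate input in which every observation is tied yields H = 0,
p = 1, flagged with `degenerate = TRUE`, rather than NaN.

**Unit of analysis.** The pipeline treats the ROI as the statistical unit,
as the classification task requires. When several ROIs come from one
micrograph or one specimen, they are pseudo-replicates for
specimen-level inference; the ROI manifest carries `image_id` so users can
aggregate to micrograph or specimen level before testing if that is the
inference they need. The package deliberately leaves that aggregation to the
caller instead of guessing.

## Classification

The 8-feature table (IDM, contrast, correlation, ASM, sum variance, EnLH,
EnHL, EnHH) feeds two models:

* **Random forest** — 100 trees, `ceiling(sqrt(8)) = 3` candidate features
  per split, no depth cap. The ROC score of a ROI is the fraction of trees
  voting for the positive class: simple and exactly reproducible given the
  seed.
* **SVM, RBF kernel** — `cost = 1`, `gamma = 1/8`. Features are standardized
  to zero mean/unit variance *using training-set statistics only*, applied
  unchanged at prediction time (the no-leakage property is asserted by a
  test that scores test rows one at a time). The ROC score is the signed
  decision value; probability calibration is unnecessary for ranking-based
  AUC and is not performed.

Evaluation reports **both** a held-out test accuracy (stratified seeded
80/20 split) and a pooled 5-fold cross-validated accuracy on the training
part. The two estimate different things and are never merged or averaged.
ROC curves sweep thresholds over unique scores with ties grouped into single
steps; the trapezoidal area equals the normalized Mann–Whitney U statistic
with ties counted 1/2, which the tests verify against a brute-force pairwise
oracle to 1e-10.

Hyperparameters were fixed once at the defaults above; there is no tuning
loop, and every fit is a pure function of (data, hyperparameters, seed).

## Numerical and reproducibility choices

* Coordinates are 0-based, row-major, with half-open extents, stated once in
  `crop_image()`/`extract_rois()` and used everywhere.
* Grayscale conversion uses ITU-R BT.601 luma weights
  (0.299, 0.587, 0.114), rounded to the nearest integer.
* ROI placement replaces manual "representative" window selection with
  seeded uniform sampling; the non-overlap mode uses rejection sampling with
  a seeded fallback to cells of the disjoint tiling when the packing is too
  tight for rejection to find.
* All seeds below 2³¹; derived seeds mix the master seed with stage and item
  indices through a fixed integer recurrence, so stages can be re-run
  independently yet reproducibly. RNG state of the caller is always
  preserved.
* Pipeline outputs are plain CSV/JSON; the manifest records MD5 checksums,
  and re-running an identical config reproduces identical checksums.

## Problem sizes

The validation suite uses sizes chosen to exercise every property at
desk scale: oracle equivalence on 200 random 16×16 images across 2–16 gray
levels and both symmetry modes; Parseval conservation on 100 random
even-dimension images; Monte-Carlo calibration of the Kruskal–Wallis type-I
error over 1,000 null replicates (3 groups × 10); direction-of-effect
recovery on 100 ROIs per class at 300×300; and the classification regime on
a 500 + 500 ROI dataset with an 80/20 split and 5-fold cross-validation,
including a label-permutation control. The acceptance script
(`scripts/acceptance.R`) re-runs the 500 + 500 workflow from scratch under a
caller-supplied seed.

## Known limitations

* Absolute feature magnitudes are not comparable across texture-analysis
  software: they depend on gray-level handling, normalization and offset
  conventions that differ between implementations. Only directions and
  relative magnitudes transfer.
* The synthetic severity grades are free parameters, not calibrated to any
  particular detergent concentration or exposure time.
* Level-1 Haar only; no multi-scale energy pyramid.
* Binary classification only; the multi-grade problem is handled by the
  group statistics, not by the classifiers.
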