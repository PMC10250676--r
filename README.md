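# stromatex

Texture-based evaluation of corneal stroma decellularization from brightfield
micrographs.

Decellularized corneas are a promising source of transplant scaffolds, but
judging how completely the keratocytes were removed — and how much the
collagen lamellae were disturbed — from H&E histology is hard: keratocytes
can occupy under 10 % of the stromal volume, so intact and treated stroma
look very similar under conventional microscopy. `stromatex` implements a
quantitative alternative for researchers working on tissue decellularization
and scaffold quality control: second-order texture statistics and wavelet
subband energies computed per region of interest (ROI), nonparametric group
comparison across treatment conditions, and supervised classification of
ROIs as intact versus decellularized.

## The method

For each square ROI (default 300 × 300 pixels, 8-bit grayscale), the package
computes eight features.

**Gray-level co-occurrence matrix (GLCM).** Let p(i, j) be the normalized
frequency with which a pixel of gray level *i* has a pixel of gray level *j*
as its immediate right-hand neighbour (offset (0, +1), asymmetric
accumulation). With marginal means μx, μy, standard deviations σx, σy, and
gray-level-sum distribution p_{x+y}:

- Angular second moment: `ASM = Σᵢ Σⱼ p(i,j)²` (textural uniformity)
- Inverse difference moment: `IDM = Σᵢ Σⱼ p(i,j) / (1 + (i−j)²)` (local homogeneity)
- Contrast: `CON = Σᵢ Σⱼ (i−j)² p(i,j)` (local intensity variation)
- Correlation: `COR = (Σᵢ Σⱼ i·j·p(i,j) − μx μy) / (σx σy)`
- Sum variance: `SVAR = Σₖ (k − SA)² p_{x+y}(k)` with sum average `SA = Σₖ k p_{x+y}(k)`

**Wavelet subband energies.** A level-1 orthonormal Haar decomposition
splits the ROI into LL/LH/HL/HH subbands; the three detail energies are
`En = Σ d² / n`, with *n* the ROI pixel count. Rough, cell-bearing texture
has high detail energies; homogenized acellular texture has low ones.

**Statistics and classification.** Features are compared across treatment
groups with Kruskal–Wallis omnibus tests, Dunn's pairwise post-hoc z tests
and Bonferroni adjustment. A random forest and an RBF-kernel SVM are trained
on the 8-feature table (stratified 80/20 split, 5-fold cross-validation on
the training part, ROC/AUC on the held-out part).

Because real decellularization micrograph sets are rarely shareable, the
package ships a seeded synthetic generator
([`generate_micrograph_set()`]) that emulates the statistical signature of
stromal texture — oriented lamellar banding, sparse dark elongated nuclei,
speckle — and its homogenization under graded decellularization severity
(`native`, `g1` … `g4`), so the full pipeline is testable end to end.

## Worked example

```r
library(stromatex)

set <- generate_micrograph_set(50, c("native", "g4"),
                               stroma_params(size = 300), seed = 42)
features <- compute_feature_table(set)

summarize_groups(features, "asm")
#> # A tibble: 2 × 4
#>   group      n     mean        sd
#>   <chr>  <int>    <dbl>     <dbl>
#> 1 g4        50 0.00257  0.000243
#> 2 native    50 0.000880 0.0000698

kw_dunn_test(features, "sum_variance")
#> <kw_dunn> sum_variance: H = 74.2574, df = 1, p = 6.857e-18 (n = 100)
#> # A tibble: 1 × 5
#>   group1 group2     z        p    p_adj
#>   <chr>  <chr>  <dbl>    <dbl>    <dbl>
#> 1 g4     native -8.62 6.86e-18 6.86e-18

report <- evaluate_classifiers(features, seed = 42)
glance(report)
#> # A tibble: 2 × 4
#>   model test_accuracy cv_accuracy   auc
#>   <chr>         <dbl>       <dbl> <dbl>
#> 1 rf                1           1     1
#> 2 svm               1           1     1
```

Reading the output: the mean ASM of the fully decellularized grade (`g4`,
0.00257) is about three times the native mean (0.00088) — removing nuclei
and homogenizing the texture concentrates co-occurrence mass in fewer cells.
Sum variance drops sharply in the treated group (negative Dunn z for
`g4 − native`), and the omnibus difference is overwhelming (H = 74.3,
p ≈ 7e-18). On this synthetic contrast the two classes are fully separable,
so both classifiers reach perfect held-out accuracy and AUC;
`autoplot(report)` draws the ROC curves and `plot_feature_groups(features)`
the per-feature group boxplots.

The whole analysis can also be run as one reproducible pipeline that writes
`features.csv`, `stats.json`, per-model reports and a checksummed manifest:

```r
cfg <- pipeline_config(n_per_group = 500, grades = c("native", "g4"),
                       params = stroma_params(size = 300), master_seed = 1)
run_texture_pipeline(cfg, "out/")
```

or from a shell via `Rscript inst/scripts/run_pipeline.R --out out/ --seed 1`.

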