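---
title: "chromocell: methods, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromocell: methods, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chromocell` quantifies and classifies cell populations from color
bright-field micrographs of dye-stained cultures, where each cell's
interior color reflects its intracellular pH.  This vignette explains the
model behind each stage, the tunable parameters and why their defaults are
what they are, what the synthetic data generator does and does not
emulate, and the numerical conventions adopted where the problem left a
genuine choice.

## 1. The segmentation model

The pipeline assumes the contrast regime of stained cultures under
bright-field optics: a bright, near-uniform background and sparse,
roughly convex cells that are darker and more saturated than the field.
Two independent per-pixel classifiers are run and only their agreement is
trusted:

* **CIELAB k-means.**  Pixels are embedded as (L\*, a\*, b\*) vectors
  (sRGB decoding, D65 white point) and clustered with Lloyd's algorithm,
  k = 2, k-means++ seeding, best of `kmeans_restarts = 10` runs by
  within-cluster sum of squares.  Nothing in an unsupervised clustering
  says which cluster is "cell", so the background cluster is identified
  as the one occupying the larger fraction of the image border — a rule
  that is correct whenever cells are sparse enough not to dominate the
  border, and deterministic (ties go to the larger cluster).
* **Otsu thresholding.**  The luminance image (Rec. 709 weights) is
  binned into 256 unit-width bins, matching 8-bit camera quantization,
  and the threshold maximizing the between-class variance is chosen.
  Polarity again follows the border rule: the side contributing fewer
  border pixels is foreground, so inverted-contrast images still work.

The **conservative mask** is the pixelwise AND of the two estimates:
a pixel enters a cell only when both paths agree, trading a slightly
eroded boundary for robustness to either path's failure mode.

**Watershed.**  Touching cells are split by marker-controlled watershed.
Markers are local maxima of the Gaussian-smoothed (σ = 1 px) Euclidean
distance transform, thinned so no two markers are closer than
`min_marker_distance = 5` px; flooding runs on the negated unsmoothed
distance transform restricted to the mask (Meyer's priority-flood,
8-connectivity, FIFO tie-break, implemented in C++).  Both marker
parameters are exposed because the right values scale with cell size: the
smoothing suppresses pixelation maxima, the minimum distance suppresses
duplicate maxima inside one cell.  If thinning leaves a connected mask
component with no marker, that component is labelled whole rather than
dropped, so the watershed is always a partition of the mask.

**Filtering.**  Regions below `min_cell_area = 50` px (debris at the
default 8–16 px cell radii) are removed, and `border_policy = "drop"`
discards border-touching regions whose intensity statistics would be
biased by truncation.  Survivors are relabelled 1..K in reading order of
their first pixel, a convention that makes label maps reproducible.

## 2. The 16 colorimetric features

Per cell and per channel (R, G, B, and luminance recomputed from RGB with
the same Rec. 709 weights as segmentation), the total, mean, median and
standard deviation of the pixel intensities — 16 features on the
[0, 255] scale.  Conventions fixed once and recorded:

* **population** standard deviation (divisor N); any classifier is
  invariant to this choice up to a constant factor;
* medians use the midpoint average for even pixel counts;
* the luminance channel depends only on the stored RGB raster, so a
  feature table is a pure function of the image and label map.

The **blue fraction** median_B / (median_R + median_G + median_B)
summarizes the dye's blue shift per cell; the ratio-of-medians form is
used (robust to outlier pixels, and consistent with summarizing each
channel by its median before combining).  Group comparisons use a paired
t-test when a pairing is available and sizes match, and a Welch two-sample
t-test otherwise — with cell counts differing between lines, literal
pairing of cells is not defined, so the unpaired fallback is the default.
Degenerate paired cases are reported by convention (all-zero differences:
t = 0, p = 1; constant nonzero differences: infinite t, p = 0, flagged)
rather than erroring.

## 3. Classification

Features are standardized (zero mean, unit variance per column; constant
columns dropped with a warning) and projected on the smallest number of
principal components reaching 99 % cumulative explained variance.  Five
models with fixed hyperparameters are evaluated — kNN (k = 5, Euclidean,
uniform weights), L1 logistic regression (C = 1), random forest (10
trees, depth ≤ 5, nodes < 5 not split), linear SVM (C = 1, tol = 1e-3),
and a single-hidden-layer neural network (200 ReLU units, softmax,
Adam, L2 α = 1e-4, 200 epochs) — under stratified 10-fold
cross-validation.  No hyperparameter is searched.

Numerical and design choices:

* **Per-fold PCA.**  The standardize+PCA transform is refit inside every
  training fold and applied to the fold's test split.  Fitting PCA once
  on all data before splitting leaks test-set structure into the
  transform; a `leaky_pca = TRUE` switch reproduces that literal
  workflow for comparison.
* **Backends.**  The L1 logistic model maps the C-parameterized objective
  onto a lasso path (λ = 1/(nC)); the random forest honors the depth and
  split-size limits; the SVM is a linear-kernel C-SVM — its printed
  "regression loss" has no meaning in classification and its iteration
  limit is not exposed by the underlying library, both recorded rather
  than silently dropped.  The neural network is implemented in-package so
  the stated architecture and optimizer hold exactly.
* **Probability scores for ROC.**  kNN and forest: vote fractions;
  logistic and neural network: native probabilities; SVM: summed pairwise
  decision values, min-max scaled over the scored set.  ROC curves are
  one-vs-rest on the pooled cross-validation scores, AUC by trapezoid
  rule with tied scores grouped; the multiclass summary is the class-size
  weighted average.
* **Scores.**  CA, precision, recall and F1 come from the pooled
  confusion matrix via one-vs-rest TP/FP/FN/TN; multiclass aggregation is
  the class-size weighted average, with classes whose precision or
  recall is undefined excluded (warned).  The binary case reduces to the
  textbook formulas exactly; the 0/0 F1 corner (no true positives) is
  taken as 0.  Score tables sort by CA, then precision.
* **Determinism.**  Fold assignment, every model fit, and every generator
  call derive from explicit seeds through a private RNG stream, so
  reports and written tables are byte-reproducible.

**In-silico co-culture validation** draws whole cells (rows) without
replacement from each class's mono-culture table into a shuffled mixed
validation set, trains on the remainder, and scores the mixture.  Drawing
whole rows preserves within-cell feature correlations; a
`marginal_resample` mode implements the alternative reading (each feature
column resampled independently within class), which breaks those
correlations and is useful as a robustness probe.

**t-SNE** (perplexity 30 by default, on the PCA scores) is provided for
visual inspection only.  It is the exact O(n²) formulation — Gaussian
affinities calibrated by per-point bisection, Student-t kernel, momentum
gradient descent with early exaggeration — which is the right tool at the
few-hundred-cell scale of these tables; nothing downstream consumes the
embedding.

## 4. The synthetic scene generator

`generate_scene()` emulates the statistical skeleton of a stained
bright-field field of view: a bright Gaussian background (mean
(200, 200, 200), sd 3), elliptical cells (semi-major axis uniform in
8–16 px, axis ratio 0.6–1, random orientation) placed by rejection
sampling under a minimum-separation policy, each filled with a per-cell
base color drawn from its class model (class mean ± sd 6) plus i.i.d.
pixel noise (sd 8), rounded and clipped to 8 bits.  The default palette —
olive-yellow (120, 110, 60), green (95, 130, 95), blue-gray
(75, 90, 125) — spans the dye's yellow→green→blue hue axis while keeping
all classes distinctly darker than the background.  That last property is
not cosmetic: with k = 2, pixel clustering can only separate cells from
background if all cell classes sit on the same side of the background in
CIELAB, which is also the regime in which the dye images themselves live
(stained cells are darker and more saturated than the field).  A palette
straddling the background in b\* (bright yellow vs deep blue cells in the
same field) breaks the two-cluster dichotomy by construction, for this
package and for the method it implements alike.  Class means are ≥ 15
intensity levels apart per channel, the separation regime the surrogate
evaluation stipulates.

What the generator does **not** emulate: optical point-spread and
defocus, intracellular texture (organelle-level dye accumulation),
illumination gradients (an optional linear shading field exists for
stress tests but is off by default), cell shapes beyond ellipses, and any
quantitative color→pH transfer (no calibration equation is modelled).
Consequently, passing tests demonstrate that the pipeline's machinery —
masks, watershed, features, cross-validation — is correct and lossless
under the stated contrast assumptions; they do not certify performance on
real micrographs, where texture, shading and shape irregularity can erode
both segmentation and class separation.

## 5. Problem sizes and reproducibility

The surrogate evaluation uses 400×400 px scenes of 40 cells and
accumulates ≥ 150 segmented cells per class over a handful of
mono-culture scenes per class (≈ 480 cells total) — comfortably past the
point where 10-fold stratification is stable, while keeping a full
pipeline run around half a minute on one core.  All CLI entry points and
`run_pipeline()` emit a manifest (config hash, seeds, package version,
input checksums, stage timings) so every artifact names the configuration
that produced it.

## 6. Known limitations

* k = 2 pixel clustering cannot handle fields whose cell classes bracket
  the background color; k is exposed in the parameters for exploration,
  but the background-identification rule assumes sparse cells.
* Watershed marker parameters are scale-dependent; very elongated or
  dumbbell-shaped cells may still oversplit.
* The SVM iteration limit is recorded but not enforced (backend
  limitation); in practice the linear problems here converge within
  tolerance.
* Paired blue-fraction testing requires an externally supplied pairing;
  across whole cell lines the Welch fallback is almost always what runs.
* t-SNE coordinates are for visualization; their scale and orientation
  are arbitrary and seed-dependent.
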