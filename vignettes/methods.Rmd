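---
title: "Methods: hybrid radiomics and deep-feature fusion for tumor MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid radiomics and deep-feature fusion for tumor MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

`fusionrad` classifies gray-level MRI images or volumes into benign and
malignant classes by combining two complementary feature families:

1. **Hand-crafted radiomics features** computed over a region of interest
   (ROI): first-order histogram statistics, absolute-gradient statistics, and
   the three classical texture-matrix families — the gray level co-occurrence
   matrix (GLCM, Haralick), the gray level run length matrix (GLRLM,
   Galloway) and the gray level size zone matrix (GLSZM, Thibault).
2. **Deep features** from a compact multi-scale residual convolutional
   network ("FusionNet") built from Seq-ResNet blocks with
   transpose-convolution up/down-sampling, trained with Adam and
   cross-entropy.

The two vectors are concatenated per sample and classified by a
multi-kernel support vector machine (SVM) under stratified 5-fold
cross-validation; the kernel (linear, polynomial, RBF) and its
hyperparameters are chosen by inner cross-validation on training folds only.

## Radiomics

Images are first discretized to `Ng` gray levels (default 32) by
equal-width binning of the ROI intensity range; the maximum maps to `Ng`,
and a constant ROI maps to level 1 with a warning.  Binning the ROI range
makes levels invariant to affine intensity transforms, which is why
radiomics is computed on the *original* intensities rather than the
z-scored ones: quantization removes the scale anyway, and the raw values
keep first-order statistics interpretable.

* **First-order** (11 features): mean, variance, min, max, 10th/50th/90th
  percentiles, histogram energy and entropy, skewness and kurtosis.
  Skewness and kurtosis use the adjusted Fisher–Pearson estimators with the
  sample standard deviation; for example kurtosis of `{0, 0, 1, 1}` is
  exactly −6.  On constant or too-short input both are imputed 0 and the
  feature name is flagged, keeping the vector length fixed for the SVM.
* **Gradient** (4): mean, variance, skewness, kurtosis of the gradient
  magnitude (central differences, one-sided at array ends) over the ROI.
* **GLCM** (4): contrast, energy (angular second moment), entropy,
  homogeneity; distance 1 over the four 2D directions (13 in 3D), counts
  symmetrized and normalized, features averaged over directions.
* **GLRLM** (5): short/long-run emphasis, gray-level and run-length
  non-uniformity, run fraction; direction-averaged.
* **GLSZM** (5): the same family with run length replaced by the size of
  Chebyshev-connected zones (8-connected in 2D, 26 in 3D); direction-free.

All three matrix builders are verified exactly against brute-force
enumeration oracles in the test suite, together with the conservation laws
(runs and zones partition the ROI voxels).

For 3D volumes the default extraction mode is per-slice ("2d"), matching a
slice-based classification pipeline; features are averaged over slices with
a non-empty ROI.  A full-3D mode is available as a switch.

## Preprocessing

The preprocessing chain is: background crop → optional denoising →
per-channel z-score over the non-zero foreground → foreground one-hot
channel → optional resize to a fixed grid.

* A voxel is *foreground* iff any channel is non-zero before
  normalization; this is well defined for multi-channel input and the
  background stays exactly 0 through normalization (tested to machine
  precision).
* The z-score uses the sample standard deviation (`ddof = 1`) with a floor
  of `1e-8` for constant channels (warned).  Whether filtering happens
  before or after normalization is an open choice; the default order is
  crop → filter → normalize → foreground channel.
* The one-hot foreground channel lets the network distinguish normalized
  voxels near zero from true background, and raises a 4-channel BraTS-style
  input to 5 channels.
* Denoising offers a plain median filter and a *soft weighted median filter*
  (SWMF): a weighted median whose weights are
  `exp(-|v - median(window)| / T)`.  The temperature `T` controls softness;
  as `T → 0` the filter reduces to the hard median (anchored by a 1e-9
  test), while moderate `T` averages among near-median values.  Windows are
  odd (≥ 3) with reflect padding (edge value repeated).
* Resizing is bilinear for image channels and nearest-neighbor for masks.
  A fixed grid is required by the stride-2 stages of the network; the
  package default analog of a 256×256 slice grid is 64×64 at desk scale.

## Augmentation

Seven training-time augmentations with fixed order (flips, Gaussian blur,
brightness, zoom, additive Gaussian noise, contrast, biased crop) and the
following defaults: per-axis flip p = 0.5; blur p = 0.15 with sigma uniform
in (0.5, 1.5); brightness p = 0.15, factor in (0.7, 1.3); zoom p = 0.15,
magnification in (1.0, 1.4) as a central crop resized back (cubic
Catmull-Rom for the image, nearest for masks); noise p = 0.15 with variance
uniform in (0, 0.33) on the normalized intensity scale; contrast p = 0.15,
factor in (0.65, 1.5) clipped to the original range; biased crop to a fixed
patch shape with p = 0.4 of containing a lesion voxel.

Two deliberate design choices:

* Gaussian noise is added to foreground voxels only, so the exact
  background/foreground partition established by preprocessing survives
  augmentation.
* The biased crop draws a lesion voxel uniformly and then a window
  uniformly among windows containing it.  For a single-voxel mask this is
  exactly uniform over qualifying windows; for extended masks it mildly
  up-weights windows near interior voxels, which is the standard anchored
  sampling used by patch-based segmentation trainers.

## The network

A Seq-ResNet block maps `C` channels to `C` channels: a 1×1 convolution
reduces to 15 channels, which split into five 3-channel subspaces.  The
first subspace passes through untouched; subspaces 2–5 undergo 1, 2, 3 and
4 factorized 3×3 stages respectively (each 3×3 realized as 3×1 then 1×3).
The single-stage subspace uses plain convolutions; the deeper subspaces use
depthwise-separable stages (depthwise 3×1 and 1×3 followed by a pointwise
1×1).  The five outputs are concatenated, restored to `C` channels by a
1×1 convolution with batch normalization, and added to the identity
shortcut — with all convolution weights zero the block *is* the identity,
which the tests assert exactly.  Batch normalization precedes each ReLU.
This hierarchical split keeps the parameter count far below a plain
two-3×3-conv residual block of equal width (also asserted).

Scale changes use back-projection modules built from transpose
convolutions (kernel 4, stride 2, padding 1) rather than plain strided
resampling: the main path changes resolution, a projection path maps the
result back, and the residual between the projection and the input is
mapped through a second scale change and merged with the main path by a
1×1 convolution.  All convolutions are bias-free (zero input provably maps
to zero output), with batch-norm/ReLU on the main and projection paths and
a linear residual path so sign information survives.

The full model: a 3×3 stem, five stages of Seq-ResNet blocks — (6, 8, 12,
8, 3) blocks, 37 in total — with back-projection downsampling after the
first three stages and one upsampling module after the fourth, then global
average pooling, a fully connected layer producing the deep feature vector
(default width 256), ReLU, and the 2-class head.  `depth_scale` shrinks
every stage's block count proportionally (minimum one block per stage) for
desk-scale experiments with identical topology; 0.25 gives 10 blocks.  The
stage widths are a package choice (the architecture's source fixes depth
but not width); the desk-scale experiments in the tests use
(16, 24, 32, 24, 16).

Training uses Adam (learning rate 1e-4), cross-entropy, at most 150
epochs, weights initialized from N(0, 0.01) (standard deviation 0.1) with
zero biases, and optional early stopping (patience 15 on a validation
split, disabled by default since the cap is the only stated stopping
rule).  All layers are manually differentiated over im2col-based
convolution kernels; with a fixed seed, initialization, shuffling and
hence the entire loss curve are bit-reproducible, which the tests check by
comparing the loss-curve prefix of a shorter rerun.

The network is 2D and operates on slices, matching a 256×256-slice
experimental setup; 3D volumes enter via slice extraction.  A native-3D
variant (3×1×1-style factorized convolutions) is a known limitation, not
implemented here.

## Fusion and classification

Deep and radiomics tables are joined on `sample_id` and concatenated.  Per
feature standardization is fitted on training folds only and applied to
held-out folds.  The kernel grid is `C ∈ {0.1, 1, 10}`, `γ ∈ {1/d, 0.01,
0.1}`, degree `∈ {2, 3}` with `coef0 = 1` for the polynomial kernel; inner
selection uses stratified 3-fold accuracy, with ties broken by kernel order
(linear, polynomial, RBF) then the smaller `C`, `γ`, degree.  The SVM dual
problem itself is solved by libsvm (via `e1071`); the kernel functions and
the decision function `f(x) = Σ αᵢ k(mᵢ, x) + b` are implemented in the
package and tested to reproduce the solver's predictions exactly.  A
leakage canary — a feature made informative only on held-out rows — is
asserted not to change inner-CV selection scores.

Scores for ROC/AP are signed decision values (a monotone surrogate for
class probability; the ranking metrics are invariant to monotone
transforms, so calibration is unnecessary).  Labels encode malignant as 1
(+1 internally).

## Metrics

Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, weighted F-measure
`(α²+1)PR/(α²P+R)` (harmonic mean at α = 1), specificity, accuracy; the
all-points precision-recall curve with AP as the area under the precision
envelope; mAP as the arithmetic mean of per-class APs; trapezoidal ROC/AUC
over distinct thresholds, which equals the normalized Mann–Whitney U
statistic with rank-averaged ties (asserted to 1e-10).  Division-by-zero
conventions: a metric whose denominator is zero is reported as 0 and
flagged via a `degenerate` attribute.

## The phantom generator

Phantoms emulate the *structure* of skull-stripped multi-modal MRI: an
exactly-zero background ring (at least the configured fraction of voxels),
a textured "tissue" foreground, and one lesion blob per sample that serves
as the ROI.  Texture is a Gaussian random field — white noise convolved
with a Gaussian kernel — mapped affinely to the target intensity mean/sd,
so class parameters act directly on the correlation structure that
co-occurrence statistics measure.  The `separability` knob widens the gap
in lesion-field correlation length (sigma 0.6 versus up to 3.0) and lesion
radius (fractions 0.18–0.28 versus up to 0.28–0.38) between the classes;
at separability 0 the classes are identically distributed and the pipeline
must report chance-level accuracy, which the acceptance suite checks
against the binomial 95% interval.  Labels alternate so both classes are
always represented.

What the phantoms do *not* emulate: anatomy, multi-class lesion structure
(edema/core/enhancing), scanner bias fields, inter-site intensity
variation, or any correlation between modalities.  Passing tests on
phantoms therefore demonstrates that the implementation recovers known
texture signal and respects its contracts — not that the method attains
any particular accuracy on real brain MRI.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen so the full suite
completes quickly on one CPU: 64×64 single-channel phantoms (n = 100 for
the training smoke, n = 200 for the fusion benchmark), `Ng = 16` for
benchmark radiomics, a depth-scale-0.25 network with stage widths
(16, 24, 32, 24, 16), feature width 64, and 3–5 training epochs.  The
3D phantom default is deliberately small (e.g. 16×16×8 to 32×32×24).
Other numerical choices: reflect padding for all filters; 0-based,
half-open crop offsets; pixel-center coordinate mapping for resizing;
tie-stable argmax in prediction; per-stage seeds derived from one master
seed; batch-norm epsilon 1e-5 and momentum 0.1.

## Known limitations

* No native-3D convolutions; volumes are handled per slice.
* DICOM series input is not supported; the readers cover NIfTI (single 4D
  file or per-channel `_000.._003` quartet).
* No wavelet/LoG filtered-image features, shape features, NGTDM/GLDM
  families, or feature selection.
* The "multi-kernel" head selects one kernel per fold; it does not learn
  kernel weights.
* Training is single-threaded and CPU-bound by design; the architecture is
  faithful but the default widths are desk-scale.
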