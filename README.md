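# fusionrad

Hybrid radiomics + deep-feature fusion for binary tumor classification of
gray-level MRI images and volumes, in R.

Radiologists and imaging scientists often have two complementary
descriptions of a lesion: *hand-crafted radiomics* — quantitative texture
and histogram statistics over a region of interest (ROI) — and *learned
deep features* from a convolutional network.  `fusionrad` implements both
and fuses them: the concatenated feature vector is classified as benign or
malignant by a multi-kernel support vector machine under stratified 5-fold
cross-validation.  A synthetic texture-phantom generator makes the entire
pipeline runnable and testable offline, with no imaging download.

## What is inside

* **Radiomics** (`quantizeImage`, `glcm`, `glrlm`, `glszm`,
  `firstOrderFeatures`, `gradientFeatures`, `extractRadiomics`):
  equal-width gray-level quantization to *N<sub>g</sub>* levels; first-order
  statistics including adjusted Fisher–Pearson skewness
  *Sk = n/((n−1)(n−2)) Σ zᵢ³* and excess kurtosis
  *K = n(n+1)/((n−1)(n−2)(n−3)) Σ zᵢ⁴ − 3(n−1)²/((n−2)(n−3))*;
  absolute-gradient statistics; the gray level co-occurrence matrix
  GLCM(i, j | d, θ), run length matrix GLRLM(i, L | θ) and size zone matrix
  GLSZM(i, S) with Chebyshev connectivity, each verified against
  brute-force enumeration oracles.
* **Preprocessing** (`cropBackground`, `znormalizeNonzero`,
  `addForegroundChannel`, `medianFilterImage`, `swmfFilterImage`,
  `resizeSlice`, `preprocessVolume`): zero-background cropping with exact
  inverse offsets, per-channel z-scoring over the non-zero foreground only,
  a foreground one-hot channel, median and soft weighted median (SWMF)
  denoising, bilinear slice resizing.
* **Augmentation** (`augmentSample` and the seven `random*` operations):
  per-axis flips (p 0.5), Gaussian blur, brightness, zoom, Gaussian noise,
  contrast (each p 0.15) and a lesion-biased crop (p 0.4), fully
  seed-deterministic.
* **Network** (`buildFusionNet`, `trainFusionNet`, `extractDeepFeatures`):
  a multi-scale residual CNN of 37 Seq-ResNet blocks — each block reduces
  to 15 channels, splits into five hierarchical subspaces processed by 0–4
  factorized 3×1/1×3 convolution stages, and re-fuses onto an identity
  shortcut — with transpose-convolution back-projection modules for
  down/upsampling, global average pooling and a fully connected feature
  head.  Layers are manually differentiated (im2col convolutions in
  RcppArmadillo); training is Adam at learning rate 1e-4 with N(0, 0.01)
  initialization and is bit-reproducible for a fixed seed.  `depth_scale`
  builds proportionally shallower models for CPU-scale work.
* **Fusion + SVM** (`fuseFeatures`, `fitMultikernelSVM`, `crossValidate`,
  `kernelEval`, `svmDecisionFunction`): sample-id-keyed fusion,
  train-fold-only standardization, kernel selection (linear / polynomial /
  RBF) by inner stratified 3-fold CV; the dual solver is libsvm (`e1071`),
  the kernels and decision function are the package's own.
* **Metrics** (`confusionCounts`, `prf`, `prCurveAP`, `meanAP`, `rocAuc`,
  `evalReport`): precision, recall, weighted F-measure
  F<sub>α</sub> = (α²+1)PR/(α²P+R), all-points average precision, mAP, and
  trapezoidal ROC/AUC (equal to the normalized Mann–Whitney U).
* **Phantoms + pipeline** (`generatePhantoms`, `writePhantomNifti`,
  `readVolume`, `runPipeline`): Gaussian-random-field phantoms with a
  controllable class-texture gap, BraTS-style per-channel NIfTI output, and
  a digest-cached end-to-end pipeline with a JSON manifest.  A thin CLI
  (`inst/scripts/fusionrad`) wraps these functions.

## A worked example

Generate 40 low-separability phantoms, extract radiomics features and
cross-validate them:

```r
library(fusionrad)
ph  <- generatePhantoms(phantomSpec(n_samples = 40, shape = c(32, 32),
                                    n_channels = 1, separability = 0.15,
                                    seed = 1))
tab <- radiomicsTable(ph, radiomicsConfig(ng = 16))
cv  <- crossValidate(tab, n_folds = 5, seed = 2)
round(cv$aggregate$mean, 3)
#> sensitivity specificity   precision    accuracy          f1         auc
#>       0.950       0.900       0.933       0.925       0.931       1.000
cv$selected
#> [1] "linear" "linear" "linear" "linear" "linear"
```

Even at a mild texture gap (`separability = 0.15`: the malignant lesions
have a slightly longer field correlation length) the texture features
separate the classes well — mean 5-fold accuracy 0.925 here, and the
inner CV picked the linear kernel in every fold.  At `separability = 0`
the same pipeline returns chance-level accuracy, which the test suite
checks against the binomial 95% interval.  The single-sample objects are
inspectable too:

```r
q <- quantizeImage(sampleImage(ph[[2]])[1, , ], sampleMask(ph[[2]]), Ng = 16)
q
#> QuantizedImage: 32 x 32 | Ng = 16 | ROI voxels = 394
round(glcmFeatures(glcm(q)), 3)
#>    glcm_contrast      glcm_energy     glcm_entropy glcm_homogeneity
#>            0.879            0.024            5.665            0.673
```

For the full hybrid path (network training, deep features, fusion) see
`runPipeline()` / the `demo` CLI subcommand, and the methods vignette
(`vignettes/methods.Rmd`) for the model details and design choices.

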