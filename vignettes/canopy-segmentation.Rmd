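---
title: "Two-stage segmentation of canopy images into background, green and senescent vegetation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage segmentation of canopy images into background, green and senescent vegetation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyseg)
```

## The problem

Nadir RGB images of crop canopies mix three visually distinct surfaces:
soil background, photosynthetically active (green) vegetation, and
senescent vegetation whose pigments have degraded towards yellow and
brown. The green fraction and the senescent fraction of such images are
standard proxies for crop development and senescence dynamics in field
phenotyping. Estimating them requires a per-pixel, three-class
segmentation — and the hard part is that senescent tissue and bare soil
share much of the brown/yellow colour range, while senescence itself is
a *continuum* from green to brown, so no simple colour threshold
separates the classes.

`canopyseg` implements a two-stage architecture for this problem:

1. **Stage 1 — vegetation versus background.** A small fully
   convolutional encoder-decoder predicts, for every pixel, vegetation
   (green *or* senescent) versus background. This stage can exploit
   spatial context (texture, organ shapes), which is exactly what is
   needed to tell senescent tissue from soil.
2. **Stage 2 — green versus senescent.** A support vector machine
   classifies each *vegetation* pixel as green or senescent from its
   colour alone, expressed in 23 channels drawn from eight colour
   representations. Colour is sufficient here because the confusion
   between the two vegetation states is chromatic, not spatial.

The two binary outputs are merged into a 3-class mask (0 = background,
1 = green, 2 = senescent). The merge is conservative by construction:
the output background set equals the stage-1 background set exactly,
and the SVM is only consulted on stage-1 vegetation pixels.

Keeping the stages separate has a practical payoff in annotation cost:
stage 1 needs dense binary masks, which are relatively cheap, while the
pixel-level green/senescent distinction is learned from *sparse grid
annotations* — a few dozen labelled pixels per image — because an SVM
on colour features needs no spatial context.

## Colour features

Every pixel is expanded into 23 channels: R, G, B; H, S, V; CIELab L,
a, b; four grayscale/luminance variants (GE, LA, LB, LC); C, M, Y, K;
BT.601 YCbCr (Yi, Cb, Cr); and NTSC YIQ (Yj, I, Q). The conventions
are fixed and documented so a fitted SVM is reproducible: H in degrees,
fractional channels on [0, 1], L on [0, 100], YCbCr on the 0–255 scale
with chroma offset 128, CIELab under the D65/2° white point, and hue 0
for achromatic pixels. Since "luminance" admits several standard
definitions, the package ships four: the Rec. 709 luminosity grayscale
(GE), the channel mean (LA), the HSL lightness (max+min)/2 (LB), and
the BT.601 luma (LC).

The shipped default subset for the classifier has 14 channels — R, G,
B, H, S, a, b, GE, M, Y, Cb, Cr, I, Q — the outcome of sequential
forward selection in the calibrated pipeline; the CMYK yellow channel Y
carries the yellow axis along which senescent tissue departs from
green. `step_forward_select()` reproduces the selection procedure
itself: greedy addition of the channel that maximises cross-validated
accuracy, fixed-size stop rule (default k = 14) or improvement
threshold, ties broken lexicographically so runs are deterministic.

## The miniature network

No deep-learning framework is assumed: the encoder-decoder's forward
and backward passes are implemented in compiled code within the
package. The tested default is deliberately miniature — one
2×-downsampling encoder level (width 8), one decoder level with a skip
connection, a 1×1 softmax head; about 3,000 parameters — so that the
full two-stage pipeline trains end to end in minutes on one CPU. The
encoder width, patch size and schedule are configurable
(`seg_config()`), and a full-scale backbone could be substituted
without changing any interface, but desk-scale verifiability is the
design priority here.

Training choices:

* **Loss.** Multi-class soft Dice, `1 - (2Σpt + ε)/(Σp + Σt + ε)`
  averaged over classes, with ε = 1 during training for numerical
  stability (the standalone `dice_loss()` helper uses ε = 1e-6 so that
  perfect/disjoint binary rasters score 0/1 to within tolerance).
* **Optimiser.** Adam (β₁ = 0.9, β₂ = 0.999) with a step-based
  geometric learning-rate decay from 0.01 to 1e-6 across the epoch
  budget. The step positions are not prescribed anywhere, so the decay
  is applied per epoch in equal geometric steps — the least arbitrary
  placement.
* **Early stopping.** Validation Dice loss with configurable patience
  (default 5 epochs); the best-validation weights are kept.
* **Augmentation.** Flips, quarter-turn rotations (applied identically
  to image and mask) and brightness/contrast jitter (image only).
* **Determinism.** All randomness flows from the config seed; identical
  config and data give bitwise-identical loss sequences.
* **Inference.** The network is fully convolutional; odd-sized inputs
  are edge-padded to even and cropped back. Images larger than the
  configured tile size are processed in overlapping tiles (default
  512-pixel tiles, 64-pixel overlap) stitched from tile centres, with
  zero-overlap stitching exactly equal to independent per-tile
  prediction. Classes are the per-pixel probability argmax, i.e. a 0.5
  threshold in the binary case.

## The pixel SVM

Stage 2 is an RBF-kernel SVM at the calibrated operating point C = 1,
γ = 1e-3 (the optimum of a leave-one-out grid search in the calibrated
pipeline, reproducible here with `tune_hyperparameters()`, ties broken
towards the smallest C then the smallest γ). The RBF kernel is the
right choice because green and senescent pixel clouds are not linearly
separable in colour space — the package's tests include an XOR-type
configuration where the linear kernel stays near chance while the RBF
kernel solves it.

Whether features were standardised in the original calibration is not
stated anywhere, so the package takes a documented position:
**z-scoring with training-set statistics is the default**, because the
channels live on wildly different scales (0–255, [0, 1], degrees) and
an RBF kernel at fixed γ is scale-sensitive. The flag
`svm_config(standardize = FALSE)` exposes the raw-scale variant; note
that γ = 1e-3 is a natural kernel width *on raw 0–255 colour scales*
(squared distances of order 10³–10⁴), which is worth knowing when
tuning on unstandardised features. Class weighting is not applied —
balance is handled at the data-split level, mirroring the calibrated
pipeline's design.

Leave-one-out scoring refits the SVM n times per grid cell, so
`tune_hyperparameters()` caps n (default 200) and suggests k-fold
scoring beyond it; n = 2 with one pixel per class would make every fold
single-class and is rejected.

## Grid annotations and splits

Sparse annotation uses a six-label schema: `green_veg`, `sen_veg`,
`background`, plus `green_sen_unsure`, `unknown` and `other`. The last
three mark pixels too ambiguous to use — mixed organ-border pixels,
extremely dark or saturated ones — and are dropped (never relabelled)
before training and evaluation; in the reference field dataset they
amount to about 16% of the points, and the synthetic generator can
emulate that rate via its label-noise parameter.

Grids have n×n points with n canonically between 8 and 11 (values
outside that range warn). Since the exact grid offsets of the reference
protocol are not documented, points are placed at the cell centres of
an n×n uniform partition — symmetric and always in-bounds; on a
512×512 image with n = 8 the first point is (32, 32) with spacing 64.
Coordinates are 0-based (row, col), row increasing downward, and the
CSV interchange format is `image_id,row,col,label,subdataset`.

`split_train_test()` reproduces the reference splitting scheme at the
pixel level with a per-subdataset train fraction — 0% (held out
entirely), 30% and ~40% in the reference configuration. Fractions are
treated as targets with the train count rounded down; the reference
dataset's published counts differ from its round percentages by a few
pixels, so exact-count reproduction is deliberately not attempted.

## Evaluation toolkit

All metrics derive from the confusion matrix with rows as reference:
per-class one-vs-rest precision, recall, F1 and accuracy (in percent),
the overall F1 as the *unweighted* mean of per-class F1, and the
overall accuracy. Because "accuracy" can mean either the plain
multi-class `trace/n` or the mean one-vs-rest accuracy — and the two
differ for three classes — both are reported (`accuracy`,
`accuracy_ovr`), with `accuracy` the headline number. The 95%
confidence half-width on an F1 score is `100·1.96·√(F1(1−F1)/n)`. A
class absent from both margins has undefined F1: reported as 0 with a
warning, or excluded from macro means under `na_absent = TRUE` (the
reference evaluation never hits this case).

Canopy fractions are exact count ratios (they sum to 1 over classes by
construction), computable from dense masks or sparse grid points, and
`fraction_regression()` reports R² = 1 − SSres/SStot, RMSE, and the
least-squares slope and offset of predicted on reference fractions.
`similitude()` applies the same machinery with one *model's* output as
the reference — it measures agreement between models, not correctness —
which is how the weakly supervised student is compared with its
teacher. `misclassification_color_profile()` recomputes HSV brightness
and saturation for evaluated pixels and contrasts the cumulative
brightness distributions of misclassified versus well-classified
pixels, the diagnostic that exposes dark-pixel and saturated-pixel
failure modes.

## Weak supervision

Dense 3-class masks are expensive; the package instead distils the
two-stage model into a direct 3-class network: `generate_pseudo_masks()`
runs the two-stage model over the stage-1 training images, and
`train_unet3c()` fits a 3-class head with the same architecture, loss
and hyperparameters on these pseudo-masks. The student can at best
reproduce its teacher (plus architectural smoothing — kernel-based
decoders blur small structures that the pixel-wise SVM preserves), so
it is evaluated by similitude against the teacher on held-out scenes.

## The synthetic scene generator

Every quantitative claim in the package is testable offline because the
generator produces canopy-like scenes with exact ground truth. Design:

* **Geometry.** Class regions are carved from two independent smoothed
  Gaussian random fields by quantile thresholding — one field separates
  vegetation from background, a second splits vegetation into green and
  senescent. Thresholded random fields give irregular, organ-like
  blobs and, crucially, borders full of mixed-colour pixels, the
  classic hard case. Thin 1–2 px segments emulate awns. Quantile
  thresholding makes realised fractions track targets closely (the
  generator contract is ±0.1 per class; deviations warn).
* **Colour.** Green pixels draw hue from 70–160°, senescent from
  20–60°, both well-saturated; the background is a soil palette of
  brownish hues at *low* saturation (0.03–0.30). The defaults straddle
  the green-to-yellow senescence continuum, and soil deliberately
  shares the senescent hue range so that colour alone cannot separate
  senescent vegetation from background — the property that motivates
  the two-stage design in the first place.
* **Illumination.** The `natural` regime draws brightness from a
  mid-range Beta distribution; the `flash` regime mixes deep shadows,
  lit canopy and near-saturated highlights, reproducing the heavier
  dark tail of flash-lit acquisition. The generator's V-quantiles are
  tested to reflect this ordering.
* **Quantisation.** Images are quantised to 8-bit so that PNG
  round-trips are exact and colour features computed from arrays and
  from files agree.

What the generator does *not* emulate: realistic organ morphology,
3-D canopy structure, cast shadows with penumbra, specular highlights
on glossy leaves, camera noise models, or chromatic aberration. Passing
the synthetic suites therefore demonstrates that the machinery is
correct and the architecture behaves as designed — not that any fixed
accuracy carries over to field imagery, whose difficulty lives exactly
in the phenomena listed above.

## Problem sizes and expected results

The shipped test and acceptance configuration uses 64 training scenes
and 16 held-out scenes of 64×64 pixels, 300 labelled pixels per class
for the SVM, and 30-epoch trainings — sizes chosen so the whole
pipeline refits from scratch in a few minutes on one CPU while leaving
each component enough signal to be discriminative. Under these
conditions the miniature stage 1 reaches vegetation F1 ≈ 98 on held-out
scenes, the SVM ≈ 98–99% held-out pixel accuracy at its C = 1, γ = 1e-3
defaults, the merged model ≈ 96–97% overall 3-class accuracy, the
distilled student ≈ 95–96% similitude with its teacher, and sparse-grid
fractions regress on whole-mask fractions with slope within a few
percent of 1 — figures
recomputed, not asserted, by `scripts/acceptance.R` and the test suite.
The colour-only baseline (`svm_all_pixels = TRUE`), which must label
every soil pixel green or senescent, collapses to ≈ 63% overall
accuracy on the same scenes — the quantitative version of the argument
for stage 1.

Residual errors concentrate where they should: mixed pixels at organ
borders, and very dark pixels where 8-bit quantisation destroys hue
(at V ≈ 0 all hues collapse towards black, so chromatic features carry
no information — one reason flash-regime shadows and `unsure` labels
exist in real protocols).

## Known limitations

* The miniature network is a verification-scale stand-in for a
  full-scale encoder-decoder; its absolute scores on real imagery are
  not meaningful, only its contracts and behaviours are.
* The SVM's calibrated hyperparameters were established on real field
  pixels; on other data the leave-one-out grid search should be rerun.
* No post-processing (component filtering, CRFs) is applied to merged
  masks; any such step would break the exact background-conservation
  property and is intentionally left out.
* R² is undefined for constant reference fractions and reported as NaN
  with a warning rather than silently coerced.
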