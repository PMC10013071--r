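---
title: "Segmentation-guided reading of tissue IIF images: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation-guided reading of tissue IIF images: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tissueIIF)
```

## The reading problem

Indirect immunofluorescence (IIF) on monkey esophagus and primate salt-split
skin is a sensitive screening test for autoimmune bullous dermatoses (AIBD).
A serum's autoantibodies bind tissue structures and are visualised with a
fluorescent anti-human conjugate; the *location* of the staining carries the
diagnosis. On salt-split skin — skin split within the lamina lucida by 1M
NaCl — pemphigoid-type antibodies stain either the epidermal side ("roof")
or the dermal side ("floor") of the artificial split. On esophagus, a smooth
linear fluorescence along the basement membrane zone (BMZ) marks pemphigoid
disease, while a mesh-like intercellular staining of the epithelium marks
pemphigus. The diagnostically decisive structures are thin lines and webs
occupying a tiny fraction of a whole-biochip image of several thousand
pixels per side, which is what makes naive whole-image classification fail
and motivates the segmentation-guided design implemented here.

`tissueIIF` implements the complete reading pipeline for both substrates,
plus a seeded synthetic scene generator with exact ground truth so the whole
system can be trained, exercised and verified at desk scale on one CPU.

## Pipeline overview

**Salt-split skin.** The green channel is resized to the segmentation
working size and segmented into roof, floor, interspace and background by an
encoder–decoder network. Attention lines are computed by binary morphology:
with `DIL` the disc dilation of diameter 3,

```
L_roof  = DIL(R) & (DIL(F) | DIL(I))
L_floor = DIL(F) & (DIL(R) | DIL(I))
```

Up to 40 patches of 64×64 px are sampled along each line on the
classification raster by Poisson-disc sampling (shortfall is padded with
empty patches to keep the fixed count). A small two-head convolutional
network scores each patch with label probabilities over
positive/negative/background/unclear and a brightness score. Aggregation
uses only patches whose argmax label is informative: with `N` the
argmax-negative and `P` the argmax-positive patches,

```
y = (1 + y_pos - y_neg) / 2,
y_pos = mean over P of the argmax probability (0 if P is empty),
y_neg = mean over N of the argmax probability (0 if N is empty),
```

and the side's brightness `b` is the mean brightness of the up-to-three
patches with the highest positive probability. Background and unclear
patches cannot influence `y` or `b`; this ignoring contract is tested
exactly.

**Esophagus.** A seven-class encoder–decoder segments the tissue layers.
The BMZ class is extracted as a binary mask and paired with the image as the
two inputs of the pattern classifier, whose independent sigmoid heads score
the 'BMZ' and 'intercellular' patterns ("negative" is the absence of calls,
so dual-positive sera are representable). Pattern strength is read off as an
upper quantile of pixel intensities inside the pattern's region — the BMZ
class itself, or the desmosome band obtained by growing the BMZ mask into
the epithelium — and calibrated onto a 1–5 score.

**Titer.** Scores convert to endpoint titers on the canonical half-log
series 1:10, 1:32, 1:100, … by index addition `d[k + round(s) - 1]`. For a
dilution series, the lowest negative dilution defines a cap: the titer is
computed from the highest positive dilution below it and clamped one step
below the first negative; with no negative image the highest-dilution image
is used open-ended. The multi-image rule in the source material is ambiguous
about which image supplies the score when a negative image exists; the cap
reading used here is documented rather than silently assumed, and the
invariant "the titer never reaches the lowest negative dilution" is tested.

## Interpretation choices in the printed formulas

Two printed expressions required a reading decision:

* `f(x_i)` appears in both aggregation sums without definition; it is read
  as the probability of the patch's argmax label, which keeps `y_pos` and
  `y_neg` in [0, 1] and matches the argmax-based definition of `N` and `P`.
  Empty `N` or `P` contribute 0, so a line with no informative patches
  yields `y = 0.5`; with no positive patch at all the side is reported
  negative regardless of `y`, because no brightness (and hence no titer) can
  be derived.
* The brightness expression lacks an operator between the sum over `P_3`
  and `|P_3|`; it is read as a mean. With fewer than three positives the
  available ones are averaged.

The decision threshold on `y` is 0.5 by default (ties positive) and
configurable; no operating point is inherited from elsewhere. Because the
operating point is a free parameter, the training entry points provide
calibration helpers (`calibrateSideThreshold()`,
`calibrateEsoThresholds()`) that choose it on the *training* scenes by
maximising balanced accuracy of the aggregated score; held-out data are
never used. The end-to-end verification runs use these calibrated
thresholds, as any deployment of a probabilistic classifier would.

## Networks and training

No deep-learning framework is assumed: the package contains a small, pure-R
convolutional layer library (3×3 convolutions evaluated as nine shifted
matrix products, ReLU, 2× average pooling, nearest upsampling with
summation skip connections, dense heads, ADAM). Backpropagation is exact;
the test suite checks analytic gradients against finite differences.

* The segmenter is an encoder–decoder with three resolution levels, two
  convolution blocks per level and summation skips (default width 8).
* The patch network is a three-stage convolutional trunk on 64×64 patches
  followed by two dense branches (label softmax; brightness regression).
  Its loss is cross-entropy plus mean squared error, equally weighted; the
  brightness target is only applied to informative (non-background) labels.
* The esophagus classifier is a four-stage trunk over the image/mask pair
  with two sigmoid heads trained with binary cross-entropy.

Pooled descriptors concatenate the per-channel mean **and maximum** of the
final feature map. The patch network adds a centre-weighted mean (a
Gaussian window at the patch centre): patch centres sit on the attention
line, so this restores the position information — band at the centre versus
band on the opposite side of the split — that translation-invariant global
pooling discards. The esophagus classifier adds two attention-weighted
means driven by the BMZ mask: one over the mask band itself (linear BMZ
staining) and one over the desmosome zone grown from it into the
epithelium (intercellular staining). The max and weighted statistics
matter because the diagnostic structures are thin: a few-pixel band moves
a global average by a few percent but dominates the maximum response.

Training losses follow the substrate assignment: categorical cross-entropy
for esophagus segmentation; for split-skin segmentation the default is the
generalized Dice loss *plus* an equally weighted cross-entropy term. The
pure generalized Dice loss (weights `1/max(area,1)^2`, implemented and
tested exactly, including its class-size robustness) turned out to be
untrainable alone at desk scale: its inverse-squared-area weights
concentrate essentially all gradient on the rarest class (the thin
interspace), and held-out Dice collapses. The cross-entropy term anchors
optimisation while the Dice term keeps the class balancing; pure GDL
remains selectable via `segConfig(loss = "generalized_dice")`.

Augmentation: flips and quarter-turn rotations for image/mask pairs; flips
plus Gaussian noise for patches. All training is reproducible from the
configured seed, and the suite asserts bit-identical weights across reruns.

## The synthetic scene generator

Real training data for this problem are clinical and not public, so the
generator is a first-class module rather than a fixture. It renders:

* split-skin geometry as a smooth random split curve with a variable
  interspace gap; a configurable fraction of the width (default 0.3)
  remains attached, where linear fluorescence continues without interspace;
* seven-layer esophagus morphology with a thin BMZ line (band thickness
  `max(2, h/170)` px) and a contour-web intercellular mesh inside the
  epithelium;
* patterns as additive linear-fluorescence bands whose contrast is
  proportional to brightness in [0, 1] (score = 1 + 4·brightness), always
  inside the ground-truth region of their class — mask consistency is a
  tested invariant;
* confounders (nuclear speckles in the epidermis/epithelium, diffuse
  unspecific staining), always labelled negative for the AIBD patterns;
* noise as additive Gaussian plus a multiplicative low-frequency shading
  field (both disabled at `noiseSd = 0`), reproducing low-contrast
  borderline appearances.

Dilution series fade pattern brightness strictly to zero at the configured
endpoint index, each element reproducible from `(seed, dilutionIndex)`.

What the generator does **not** emulate: realistic tissue texture,
stitching artefacts, focus variation, conjugate background, or the
morphological variance of real biochips. Passing the synthetic end-to-end
checks therefore demonstrates that the pipeline's machinery — segmentation,
morphology, sampling, aggregation, titer logic — is implemented correctly
and trainable; it does not certify clinical accuracy on real tissue, which
in the package is represented only by the published validation confusion
matrices that `confusionMetrics()` reproduces.

## Desk-scale study conditions

The default verification runs (test suite and `scripts/acceptance.R`) use a
512×512 synthetic canvas, a 128×128 segmentation working size and the full
2048×2048 classification raster with 64×64 patches (a 64-px patch on a
smaller raster would span both sides of the split and confound the two
patterns). Per substrate they train on 96 scenes and evaluate on 40
held-out scenes; the segmenter trains 12 epochs, the patch networks 25
(minibatch 16), the esophagus classifier 36. These sizes were chosen as a
desk-scale configuration that a single CPU handles in minutes per model;
all sizes are configurable up to the full-scale values, and the geometric
contracts are size-independent.

Numerical conventions worth knowing: coordinates are (row, col) with origin
top-left; masks resample by nearest neighbour, intensities bilinearly;
non-square inputs are resized anisotropically to the square working sizes
and attention geometry stays in working coordinates; the "disc of 3 px
diameter" structuring element is the Euclidean disc of radius 1.5 on the
pixel grid, i.e. the full 3×3 neighbourhood; quantiles use type-7
interpolation; `s` rounds half-up before titer indexing; Poisson-disc
sampling builds a maximal sample by seeded dart throwing and truncates to
the fixed count, with radius `arc length / (n + 1)` clamped to [8, 64] px
when not given.

## Known limitations

* Pattern-call accuracy on synthetic scenes is an upper bound argument for
  machinery, not clinical performance.
* The encoder–decoder is a scaled-down stand-in for a production
  segmentation network; with width 8 at 128 px it resolves the synthetic
  geometry but would need the full working sizes and more capacity for real
  tissue.
* The brightness calibration knots mapping raw intensity onto the 1–5 score
  are configuration values; no clinical calibration is shipped.
* The endomysial IgA pattern and IgA conjugates generally are out of scope,
  as is stitching of raw microscope fields.
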