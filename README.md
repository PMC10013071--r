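# tissueIIF

Computer-aided reading of indirect immunofluorescence (IIF) patterns on the
two tissue substrates used to screen for autoimmune bullous dermatoses
(AIBD): **primate salt-split skin** and **monkey esophagus**.

On salt-split skin, pemphigoid-type autoantibodies stain the epidermal
("roof") or dermal ("floor") side of the artificial split produced by 1M
NaCl. On esophagus, linear staining of the basement membrane zone (BMZ)
marks pemphigoid disease and a mesh-like intercellular staining of the
epithelium marks pemphigus. The decisive structures are thin lines covering
a tiny fraction of a whole-biochip image, so the package implements a
segmentation-guided design rather than whole-image classification:

* an encoder–decoder network segments the tissue (4 classes for split skin,
  7 for esophagus);
* **split skin** — attention lines are computed by dilation algebra,
  `L_roof = DIL(R) ∩ (DIL(F) ∪ DIL(I))`,
  `L_floor = DIL(F) ∩ (DIL(R) ∪ DIL(I))`; up to 40 patches of 64×64 px are
  Poisson-disc-sampled along each line and scored by a two-head network
  (label probabilities over positive/negative/background/unclear plus a
  brightness score). Patch results aggregate to
  `y = (1 + y_pos − y_neg) / 2`, where `y_pos`/`y_neg` average the argmax
  probabilities of the positive/negative patches and background/unclear
  patches are ignored; the side brightness `b` averages the three patches
  with the highest positive probability;
* **esophagus** — the segmented BMZ becomes a binary attention mask paired
  with the image as the two inputs of a classifier with independent sigmoid
  heads for 'BMZ' and 'intercellular'; pattern strength is an upper quantile
  of the intensities inside the pattern's region, calibrated to a 1–5
  score;
* **titer** — scores convert to endpoint titers on the canonical series
  1:10, 1:32, 1:100, … via `d[k + round(s) − 1]`; over a dilution series the
  first negative dilution caps the estimate;
* agreement with expert reading is summarised as accuracy, positive percent
  agreement (PPA) and negative percent agreement (NPA);
* a **seeded synthetic scene generator** renders both substrates with exact
  ground truth (masks, pattern labels, brightness, dilution series), so the
  whole pipeline trains and verifies on one CPU.

## Worked example

```r
library(tissueIIF)

# a synthetic epidermal-positive split-skin biochip with ground truth
spec  <- sceneSpec("split_skin", pattern = "epidermal",
                   patternBrightness = 0.8, size = c(512L, 512L))
scene <- generateImage(spec, seed = 7)

# segment from ground truth and walk the geometric pipeline
seg   <- truthSegmentation(scene$truth$segMask, "split_skin", segSize = 128L)
lines <- computeAttentionLines(seg, scaleFactor = 4)
lines
#> AttentionLines: |roof| = 489 px, |floor| = 470 px (x4 to raster)

coords <- lineCoordinates(lines, "roof")
img512 <- resizeTo(pixels(scene$image), c(512L, 512L))
patches <- samplePatches(img512, coords, nTarget = 40L, seed = 3)
sum(!sapply(patches, `[[`, "isPadding"))
#> [1] 31

# titer arithmetic on the canonical dilution series
titerSingle(k = 1, s = 3)
#> TiterResult [pattern]: 1:100 (single_image)

# agreement statistics from published validation counts
vt <- validationTables()
round(confusionMetrics(vt$tp[1], vt$fp[1], vt$fn[1], vt$tn[1]), 1)
#> accuracy      PPA      NPA
#>     95.4     96.9     94.8
```

`31` real patches means the roof attention line supports 31 centres at the
Poisson radius; the list is padded to the fixed count of 40 with empty
patches that the aggregation ignores. The `95.4 / 96.9 / 94.8` triple is the
combined split-skin agreement of the published clinical validation,
recomputed from its confusion-matrix counts.

Training the full pipeline end-to-end on synthetic scenes (segmenter, patch
networks, esophagus classifier) is what `scripts/acceptance.R` and the
acceptance tests do; see the methods vignette
(`vignettes/tissue-iif-methods.Rmd`) for the models, parameters and design
decisions.

## Command-line interface

A thin wrapper over the exported functions ships in
`inst/scripts/iifseg` with subcommands `generate`, `train-seg`,
`train-sss`, `train-eso`, `predict-sss`, `predict-eso` and `evaluate`
(YAML config, JSON/CSV outputs, text model stores).

## Scope

The package reads pre-stitched whole-biochip green-channel images. Stitching
of raw microscope fields, IgA conjugates and the endomysial pattern, and any
clinical calibration of the brightness score are out of scope.
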