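# Desk-scale study conditions for the end-to-end checks: 512 px synthetic
# canvas, 128 px segmentation working size, 512 px patch raster with 64 px
# patches (the same 4x scale mapping as the full-size pipeline), 96 training
# and 40 held-out images per substrate. Trained models are cached so several
# test blocks can share one training run.

e2eConditions <- function(substrate, seed = 1L) {
  if (substrate == "split_skin") {
    list(train = c(epidermal = 28L, dermal = 24L, none = 32L, both = 12L),
         test = c(epidermal = 12L, dermal = 10L, none = 12L, both = 6L),
         segSeed = seed + 100L, trainSeed = seed + 11L,
         testSeed = seed + 99L)
  } else {
    list(train = c(BMZ = 28L, intercellular = 24L, none = 32L, both = 12L),
         test = c(BMZ = 12L, intercellular = 10L, none = 12L, both = 6L),
         segSeed = seed + 200L, trainSeed = seed + 12L,
         testSeed = seed + 98L)
  }
}

e2eSplitSkin <- function(seed = 1L) {
  cachedScene(paste0("e2e-sss-", seed), {
    cond <- e2eConditions("split_skin", seed)
    tr <- generateScenes("split_skin", cond$train, size = c(512L, 512L),
                         seed = cond$trainSeed)
    te <- generateScenes("split_skin", cond$test, size = c(512L, 512L),
                         seed = cond$testSeed)
    seg <- trainSegmenter(tr, segConfig("split_skin", segSize = 128L,
                                        epochs = 12L, seed = cond$segSeed))
    ds <- buildPatchDatasets(tr, c("roof", "floor"), segSize = 128L,
                             clsSize = 2048L, nLine = 10L,
                         seed = seed + 21L)
    roof <- trainPatchNet(ds$roof, "roof", patchConfig(epochs = 30L,
                                                       seed = seed + 31L))
    floor <- trainPatchNet(ds$floor, "floor", patchConfig(epochs = 30L,
                                                          seed = seed + 32L))
    th <- calibrateSSSThresholds(tr, roofModel = roof, floorModel = floor,
                                 segModel = seg, clsSize = 2048L,
                                 seed = seed + 51L)
    preds <- character(length(te))
    for (i in seq_along(te)) {
      pr <- predictSSS(te[[i]]$image, seg, roof, floor, clsSize = 2048L,
                       nPatches = 40L, threshold = th,
                       seed = seed + 1000L + i)
      preds[i] <- pr$pattern
    }
    truth <- vapply(te, `[[`, character(1), "pattern")
    dice <- vapply(te, function(sc)
      segmentationDice(segmentImage(seg, sc$image), sc$truth$segMask),
      numeric(1))
    list(seg = seg, roof = roof, floor = floor, te = te, threshold = th,
         preds = preds, truth = truth, dice = dice,
         accuracy = mean(preds == truth))
  })
}

e2eEsophagus <- function(seed = 1L) {
  cachedScene(paste0("e2e-eso-", seed), {
    cond <- e2eConditions("esophagus", seed)
    tr <- generateScenes("esophagus", cond$train, size = c(512L, 512L),
                         seed = cond$trainSeed)
    te <- generateScenes("esophagus", cond$test, size = c(512L, 512L),
                         seed = cond$testSeed)
    seg <- trainSegmenter(tr, segConfig("esophagus", segSize = 128L,
                                        epochs = 12L, seed = cond$segSeed))
    cls <- trainEsoClassifier(tr, seg, esoConfig(epochs = 36L, lr = 3e-3,
                                                 seed = seed + 41L))
    th <- calibrateEsoThresholds(tr, seg, cls)
    predOk <- logical(length(te))
    for (i in seq_along(te)) {
      pr <- predictEso(te[[i]]$image, seg, cls, thresholds = th)
      predOk[i] <- identical(
        sort(as.character(patternCalls(pr$classification))),
        sort(as.character(te[[i]]$truth$patternLabels)))
    }
    dice <- vapply(te, function(sc)
      segmentationDice(segmentImage(seg, sc$image), sc$truth$segMask),
      numeric(1))
    list(seg = seg, cls = cls, te = te, dice = dice,
         accuracy = mean(predOk))
  })
}
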