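lineSeg <- function(bmzRow = 100L, epiRows = 101:200, h = 256L, w = 256L) {
  lab <- matrix(0L, h, w)
  lab[epiRows, ] <- 1L
  lab[bmzRow, ] <- 2L
  truthSegmentation(lab, "esophagus")
}

test_that("BMZ mask extraction keeps exactly the BMZ class", {
  seg <- lineSeg()
  bm <- extractBMZMask(seg)
  expect_identical(bm, classMap(seg) == 3L)   # class index of "BMZ"
  noBmz <- truthSegmentation(matrix(0L, 32, 32), "esophagus")
  expect_equal(sum(extractBMZMask(noBmz)), 0)
  # truth identity on a synthetic scene
  sc <- cachedScene("eso-ident", {
    generateImage(sceneSpec("esophagus", "BMZ", 1, size = c(256L, 256L)),
                  seed = 2)
  })
  segT <- truthSegmentation(sc$truth$segMask, "esophagus")
  expect_identical(extractBMZMask(segT),
                   sc$truth$segMask == substrateClasses("esophagus")[["BMZ"]])
})

test_that("nearest-neighbour upscaling preserves area up to border effects", {
  seg <- lineSeg()
  n512 <- sum(extractBMZMask(seg, clsSize = 512L))
  n256 <- sum(extractBMZMask(seg))
  expect_lte(abs(n512 - 4 * n256), 4 * 2 * (256 + 1))
  expect_error(extractBMZMask(truthSegmentation(matrix(0L, 8, 8),
                                                "split_skin")),
               "esophagus")
})

test_that("desmosome region is the epithelial band adjacent to the BMZ", {
  seg <- lineSeg(bmzRow = 100L, epiRows = 101:200)
  reg <- desmosomeRegion(seg, bandPx = 10L)
  expRows <- 101:110
  expect_true(all(which(apply(reg, 1, any)) == expRows))
  expect_true(all(reg[expRows, ]))
  # region stays inside the epithelium and off the BMZ
  cls <- classMap(seg)
  expect_true(all(cls[reg] == 2L))        # epithelium index
  expect_error(desmosomeRegion(seg, 0L), "bandPx")
  # no epithelium: empty region
  labNoEpi <- matrix(0L, 64, 64); labNoEpi[30, ] <- 2L
  expect_equal(sum(desmosomeRegion(truthSegmentation(labNoEpi, "esophagus"),
                                   5L)), 0)
})

test_that("desmosome region grows monotonically with the band width", {
  seg <- lineSeg()
  r5 <- desmosomeRegion(seg, 5L)
  r10 <- desmosomeRegion(seg, 10L)
  expect_true(all(r10[r5]))
  expect_gt(sum(r10), sum(r5))
})

test_that("region intensity is the stated quantile with shift equivariance", {
  img <- matrix(0.4, 20, 20)
  reg <- matrix(TRUE, 20, 20)
  ri <- regionIntensity(img, reg, q = 0.7)
  expect_equal(rawIntensity(ri), 0.4)
  # grid of 100 distinct values against the order-statistics oracle
  vals <- seq(0, 0.99, by = 0.01)
  img2 <- matrix(vals, 10, 10)
  ri2 <- regionIntensity(img2, matrix(TRUE, 10, 10), q = 0.95)
  expect_equal(rawIntensity(ri2), oracleQuantile7(vals, 0.95))
  # shift equivariance
  d <- 0.003
  ri3 <- regionIntensity(img2 + d, matrix(TRUE, 10, 10), q = 0.95)
  expect_equal(rawIntensity(ri3), rawIntensity(ri2) + d)
  # default calibration endpoints: raw 0 -> 1, raw 1 -> 5
  expect_equal(brightnessScore(regionIntensity(matrix(0, 4, 4),
                                               matrix(TRUE, 4, 4))), 1)
  expect_equal(brightnessScore(regionIntensity(matrix(1, 4, 4),
                                               matrix(TRUE, 4, 4))), 5)
  expect_error(regionIntensity(img, matrix(FALSE, 20, 20)), "empty")
})

test_that("classifier probabilities are squashed and calls match thresholds", {
  cfg <- esoConfig(channels = 4L, hidden = 8L, netSize = 64L)
  set.seed(5)
  model <- structure(list(params = esoNetInit(cfg), config = cfg,
                          curve = numeric(0)), class = "esoModel")
  img <- matrix(runif(64 * 64), 64, 64)
  msk <- matrix(FALSE, 64, 64); msk[30, ] <- TRUE
  cl <- classifyEso(model, img, msk)
  expect_true(all(patternProbs(cl) >= 0 & patternProbs(cl) <= 1))
  expect_identical(cl@negative, length(patternCalls(cl)) == 0L)
  # zero-initialised heads give probability 0.5: calls at default threshold
  expect_equal(unname(patternProbs(cl)), c(0.5, 0.5))
  expect_identical(sort(patternCalls(cl)), c("BMZ", "intercellular"))
})

test_that("esophagus training is reproducible and learns the all-negative constant", {
  scenes <- cachedScene("eso-neg6", {
    generateScenes("esophagus", c(none = 6L), size = c(256L, 256L),
                   seed = 19)
  })
  cfg <- esoConfig(channels = 4L, hidden = 8L, netSize = 64L, epochs = 4L,
                   seed = 3, augment = FALSE)
  m1 <- trainEsoClassifier(scenes, NULL, cfg)
  m2 <- trainEsoClassifier(scenes, NULL, cfg)
  expect_identical(m1$params, m2$params)
  probs <- sapply(scenes, function(sc) {
    segT <- truthSegmentation(sc$truth$segMask, "esophagus")
    patternProbs(classifyEso(m1, sc$image, extractBMZMask(segT)))
  })
  expect_lt(max(probs), 0.5)
  expect_error(trainEsoClassifier(list(), NULL, cfg), "empty")
})

test_that("esophagus-network gradients match finite differences", {
  set.seed(13)
  cfg <- esoConfig(channels = 4L, hidden = 6L, netSize = 64L,
                   augment = FALSE)
  p <- esoNetInit(cfg)
  p$head <- denseParam(6L, 2L)
  img <- matrix(runif(64 * 64), 64, 64)
  msk <- matrix(0, 64, 64); msk[30:31, ] <- 1
  targets <- c(BMZ = 1, intercellular = 0)
  lossOf <- function(p) {
    fw <- esoNetForward(p, img, msk, cfg)
    -sum(targets * log(fw$probs + 1e-12) +
           (1 - targets) * log(1 - fw$probs + 1e-12))
  }
  fw <- esoNetForward(p, img, msk, cfg)
  bw <- esoNetBackward(p, fw, targets, cfg)
  eps <- 1e-6
  for (nm in c("c1", "c4", "h")) {
    g <- if (nm == "h") bw$grads[[nm]]$W else bw$grads[[nm]]$W[[5]]
    i <- which.max(abs(g))
    bump <- function(p, d) {
      if (nm == "h") p[[nm]]$W[i] <- p[[nm]]$W[i] + d
      else p[[nm]]$W[[5]][i] <- p[[nm]]$W[[5]][i] + d
      p
    }
    num <- (lossOf(bump(p, eps)) - lossOf(bump(p, -eps))) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})
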