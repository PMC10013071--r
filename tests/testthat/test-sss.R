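bandSeg <- function() {
  # full-width horizontal bands: roof rows 1-4, interspace 5-6, floor 7-10
  lab <- matrix(0L, 10, 10)
  lab[1:4, ] <- 1L; lab[7:10, ] <- 2L; lab[5:6, ] <- 3L
  truthSegmentation(lab, "split_skin")
}

test_that("attention lines follow the dilation set equations on band geometry", {
  al <- computeAttentionLines(bandSeg(), scaleFactor = 1)
  # 1-D band arithmetic: DIL(R)=rows 1-5, DIL(I)=rows 4-7, DIL(F)=rows 6-10
  expRoof <- matrix(FALSE, 10, 10); expRoof[4:5, ] <- TRUE
  expFloor <- matrix(FALSE, 10, 10); expFloor[6:7, ] <- TRUE
  expect_identical(roofLine(al), expRoof)
  expect_identical(floorLine(al), expFloor)
})

test_that("attention lines vanish without opposing regions", {
  empty <- truthSegmentation(matrix(0L, 12, 12), "split_skin")
  al <- computeAttentionLines(empty)
  expect_equal(sum(roofLine(al)), 0)
  expect_equal(sum(floorLine(al)), 0)
  roofOnly <- matrix(0L, 12, 12); roofOnly[4:8, ] <- 1L
  al2 <- computeAttentionLines(truthSegmentation(roofOnly, "split_skin"))
  expect_equal(sum(roofLine(al2)), 0)
  eso <- truthSegmentation(matrix(0L, 12, 12), "esophagus")
  expect_error(computeAttentionLines(eso), "split-skin")
})

test_that("attention lines equal the brute-force oracle on random masks", {
  set.seed(31)
  for (i in 1:40) {
    h <- sample(8:64, 1); w <- sample(8:64, 1)
    lab <- matrix(sample(0:3, h * w, TRUE,
                         prob = c(0.3, 0.3, 0.3, 0.1)), h, w)
    al <- computeAttentionLines(truthSegmentation(lab, "split_skin"))
    orc <- oracleAttentionLines(lab, dil = function(m) bruteDilate(m, 3L))
    expect_identical(roofLine(al), orc$roof)
    expect_identical(floorLine(al), orc$floor)
  }
})

test_that("line coordinates map to the classification raster", {
  al <- computeAttentionLines(bandSeg(), scaleFactor = 4)
  co <- lineCoordinates(al, "roof")
  expect_true(all(co[, "row"] %in% round((c(4, 5) - 0.5) * 4 + 0.5)))
  expect_equal(nrow(co), 20L)   # 2 rows x 10 cols, unique after mapping
})

test_that("Poisson-disc sampling honours count, spacing and padding", {
  # empty line: all padding
  ps0 <- samplePatches(matrix(0, 256, 256), NULL, nTarget = 40L)
  expect_length(ps0, 40L)
  expect_true(all(sapply(ps0, `[[`, "isPadding")))
  # dense straight line, explicit radius: full real count, spacing >= radius
  img <- matrix(runif(300 * 2100), 300, 2100)
  coords <- cbind(row = rep(150L, 2000L), col = 51:2050)
  ps <- samplePatches(img, coords, nTarget = 40L, radius = 24, seed = 5)
  real <- ps[!sapply(ps, `[[`, "isPadding")]
  expect_length(real, 40L)
  ctr <- t(sapply(real, `[[`, "center"))
  dmat <- as.matrix(dist(ctr))
  expect_gte(min(dmat[upper.tri(dmat)]), 24)
  # determinism and patch content
  ps2 <- samplePatches(img, coords, nTarget = 40L, radius = 24, seed = 5)
  expect_identical(lapply(ps, `[[`, "center"), lapply(ps2, `[[`, "center"))
  p1 <- real[[1]]
  expect_equal(dim(p1$pixels), c(64L, 64L))
  expect_equal(p1$pixels[32, 32],
               img[p1$center["row"], p1$center["col"]])
  # short line: padded up to the fixed count
  shortCo <- cbind(row = rep(100L, 30L), col = 101:130)
  ps3 <- samplePatches(img, shortCo, nTarget = 40L, radius = 16, seed = 2)
  expect_length(ps3, 40L)
  expect_gt(sum(sapply(ps3, `[[`, "isPadding")), 30L)
  # borders: centers near the edge still give in-bounds 64x64 patches
  edgeCo <- cbind(row = c(1L, 300L), col = c(1L, 2100L))
  ps4 <- samplePatches(img, edgeCo, nTarget = 2L, radius = 1, seed = 1)
  expect_true(all(sapply(ps4, function(p) all(dim(p$pixels) == 64L))))
})

test_that("aggregation reproduces the printed formula on hand-computed cases", {
  # (0.9, 0.7 positive; 0.6 negative): y_pos=0.8, y_neg=0.6, y=0.6
  r <- mkResults(pos = c(0.9, 0.7), neg = 0.6)
  sr <- aggregatePatches(r, "roof")
  expect_equal(sr@yPos, 0.8)
  expect_equal(sr@yNeg, 0.6)
  expect_equal(aggregationScore(sr), 0.6)
  expect_equal(sr@nInformative, 3L)
  # all unclear: y = 0.5 with nothing informative
  r2 <- mkResults(unc = c(0.9, 0.8, 0.7))
  sr2 <- aggregatePatches(r2, "roof")
  expect_equal(aggregationScore(sr2), 0.5)
  expect_equal(sr2@nInformative, 0L)
  expect_true(is.na(brightnessScore(sr2)))
  expect_equal(sideCall(sr2), "negative")  # no positives -> negative
})

test_that("brightness averages the top-3 positives by positive probability", {
  r <- mkResults(pos = c(0.9, 0.8, 0.7, 0.6, 0.5), bright = c(1, 2, 3, 4, 5))
  sr <- aggregatePatches(r, "floor")
  expect_equal(brightnessScore(sr), (1 + 2 + 3) / 3)
  # fewer than three positives: average what exists
  r2 <- mkResults(pos = c(0.9, 0.6), bright = c(2, 4))
  expect_equal(brightnessScore(aggregatePatches(r2, "roof")), 3)
})

test_that("background and unclear patches never influence y or b", {
  set.seed(41)
  for (i in 1:20) {
    nP <- sample(0:4, 1); nN <- sample(0:4, 1)
    r <- mkResults(pos = runif(nP, 0.5, 1), neg = runif(nN, 0.5, 1),
                   bright = if (nP + nN > 0) runif(nP + nN, 1, 5) else NULL)
    base <- aggregatePatches(r, "roof")
    extra <- mkResults(bg = runif(3, 0.5, 1), unc = runif(2, 0.5, 1))
    both <- aggregatePatches(rbind(r, extra), "roof")
    expect_equal(aggregationScore(both), aggregationScore(base))
    expect_equal(both@b, base@b)
    expect_identical(sideCall(both), sideCall(base))
  }
})

test_that("y stays in [0,1] and is monotone in each patch probability", {
  set.seed(42)
  for (i in 1:30) {
    nP <- sample(1:5, 1); nN <- sample(1:5, 1)
    pv <- runif(nP, 0.4, 0.95); nv <- runif(nN, 0.4, 0.95)
    y0 <- aggregationScore(aggregatePatches(mkResults(pos = pv, neg = nv),
                                            "roof"))
    expect_gte(y0, 0); expect_lte(y0, 1)
    # raising a positive patch's confidence raises y; raising a negative
    # patch's confidence lowers y
    pv2 <- pv; pv2[1] <- pv2[1] + 0.04
    expect_gt(aggregationScore(aggregatePatches(mkResults(pos = pv2,
                                                          neg = nv),
                                                "roof")), y0)
    nv2 <- nv; nv2[1] <- nv2[1] + 0.04
    expect_lt(aggregationScore(aggregatePatches(mkResults(pos = pv,
                                                          neg = nv2),
                                                "roof")), y0)
  }
})

test_that("y at the threshold is called positive", {
  r <- mkResults(pos = 0.8, neg = 0.6)   # y = (1 + 0.8 - 0.6)/2 = 0.6
  sr <- aggregatePatches(r, "roof", threshold = 0.6)
  expect_equal(sideCall(sr), "positive")
})

test_that("patch classification is pure and sums to one", {
  cfg <- patchConfig(channels = 4L, hidden = 8L, patchSize = 32L)
  set.seed(3)
  model <- structure(list(params = patchNetInit(cfg), side = "roof",
                          config = cfg, curve = numeric(0)),
                     class = "patchModel")
  px <- matrix(runif(32 * 32), 32, 32)
  res <- classifyPatches(model, list(px, px))
  expect_equal(as.numeric(res[1, 1:4]), as.numeric(res[2, 1:4]))
  expect_equal(unname(rowSums(res[, 1:4])), c(1, 1), tolerance = 1e-9)
})

test_that("patch-network training is seeded-reproducible and fits a constant brightness", {
  set.seed(6)
  n <- 30L
  ds <- list(patches = replicate(n, matrix(runif(1024), 32, 32),
                                 simplify = FALSE),
             labelIdx = rep(c(1L, 2L), length.out = n),
             bright = rep(3, n))
  cfg <- patchConfig(channels = 4L, hidden = 8L, epochs = 8L,
                     patchSize = 32L, seed = 11, augment = FALSE)
  m1 <- trainPatchNet(ds, "roof", cfg)
  m2 <- trainPatchNet(ds, "roof", cfg)
  expect_identical(m1$params, m2$params)
  res <- classifyPatches(m1, ds$patches)
  expect_lt(mean((res$brightness - 3)^2), 0.1)
  expect_error(trainPatchNet(list(patches = list(), labelIdx = integer(0),
                                  bright = numeric(0)), "roof", cfg),
               "empty")
})

test_that("patch-network gradients match finite differences", {
  set.seed(9)
  cfg <- patchConfig(channels = 4L, hidden = 6L, patchSize = 32L,
                     augment = FALSE)
  p <- patchNetInit(cfg)
  p$lab2 <- denseParam(6L, 4L); p$br2 <- denseParam(6L, 1L)
  px <- matrix(runif(1024), 32, 32)
  lossOf <- function(p) {
    fw <- patchNetForward(p, px, cfg)
    -log(fw$probs[2L] + 1e-12) + (fw$bright - 2.5)^2
  }
  fw <- patchNetForward(p, px, cfg)
  bw <- patchNetBackward(p, fw, 2L, 2.5, cfg)
  eps <- 1e-6
  for (nm in c("c1", "c3")) {
    k <- 5L
    i <- which.max(abs(bw$grads[[nm]]$W[[k]]))
    p1 <- p; p1[[nm]]$W[[k]][i] <- p1[[nm]]$W[[k]][i] + eps
    p2 <- p; p2[[nm]]$W[[k]][i] <- p2[[nm]]$W[[k]][i] - eps
    num <- (lossOf(p1) - lossOf(p2)) / (2 * eps)
    expect_equal(bw$grads[[nm]]$W[[k]][i], num, tolerance = 1e-4)
  }
  for (nm in c("lab1", "br1")) {
    i <- which.max(abs(bw$grads[[nm]]$W))
    p1 <- p; p1[[nm]]$W[i] <- p1[[nm]]$W[i] + eps
    p2 <- p; p2[[nm]]$W[i] <- p2[[nm]]$W[i] - eps
    num <- (lossOf(p1) - lossOf(p2)) / (2 * eps)
    expect_equal(bw$grads[[nm]]$W[i], num, tolerance = 1e-4)
  }
})
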