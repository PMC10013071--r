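smallSpec <- function(...) sceneSpec(size = c(256L, 256L), ...)

test_that("scene generation is deterministic and validates its inputs", {
  sp <- smallSpec("split_skin", "epidermal", 0.8)
  a <- generateImage(sp, seed = 3)
  b <- generateImage(sp, seed = 3)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(a$truth$segMask, b$truth$segMask)
  c_ <- generateImage(sp, seed = 4)
  expect_false(identical(pixels(a$image), pixels(c_$image)))
  expect_error(sceneSpec("split_skin", "BMZ"), "not valid")
  expect_error(sceneSpec("esophagus", "epidermal"), "not valid")
  expect_error(smallSpec("split_skin", "epidermal", 0), "brightness")
  expect_error(sceneSpec("split_skin", size = c(64L, 64L)))
})

test_that("noise-free negative scenes are piecewise constant at tissue level", {
  sp <- smallSpec("split_skin", "none", noiseSd = 0)
  sc <- generateImage(sp, seed = 1)
  px <- pixels(sc$image)
  roof <- sc$truth$segMask == 1L
  # no band rendered: the roof is exactly its base intensity everywhere,
  # including along the split boundary
  expect_equal(unique(as.vector(px[roof])), 0.32)
  expect_lte(length(unique(as.vector(px))), 4L)
})

test_that("pattern bands are brighter than the opposite side and monotone in brightness", {
  contrasts <- sapply(c(0.3, 0.6, 1.0), function(b) {
    sp <- smallSpec("split_skin", "epidermal", b, noiseSd = 0,
                    geometrySeed = 9L)
    sc <- generateImage(sp, seed = 2)
    px <- pixels(sc$image)
    bandRoof <- sc$truth$bands$epidermal
    bandFloor <- sc$truth$bands$dermal
    expect_gt(mean(px[bandRoof]) - mean(px[bandFloor]), 0)
    mean(px[bandRoof]) - mean(px[sc$truth$segMask == 1L & !bandRoof])
  })
  expect_true(all(diff(contrasts) > 0))
})

test_that("rendered bands lie inside their ground-truth class regions", {
  sp <- smallSpec("split_skin", "both", c(epidermal = 1, dermal = 1))
  sc <- generateImage(sp, seed = 5)
  expect_true(all(sc$truth$segMask[sc$truth$bands$epidermal] == 1L))
  expect_true(all(sc$truth$segMask[sc$truth$bands$dermal] == 2L))
  spe <- smallSpec("esophagus", "both", c(BMZ = 1, intercellular = 1))
  sce <- generateImage(spe, seed = 5)
  cls <- substrateClasses("esophagus")
  expect_true(all(sce$truth$segMask[sce$truth$bands$BMZ] == cls[["BMZ"]]))
  expect_true(all(sce$truth$segMask[sce$truth$bands$intercellular] ==
                    cls[["epithelium"]]))
  # labels drawn only from the class table
  expect_true(all(sce$truth$segMask %in% cls))
})

test_that("brightness scores accompany exactly the active patterns", {
  sc <- generateImage(smallSpec("split_skin", "dermal", 0.5), seed = 1)
  expect_identical(sc$truth$patternLabels, "dermal")
  expect_equal(unname(sc$truth$brightnessScores["dermal"]), 1 + 4 * 0.5)
  neg <- generateImage(smallSpec("split_skin", "none"), seed = 1)
  expect_length(neg$truth$brightnessScores, 0L)
})

test_that("dilution series fades strictly to the endpoint", {
  base <- smallSpec("split_skin", "epidermal", 1.0)
  ser <- generateDilutionSeries(base, titerIndex = 3L, nDilutions = 3L,
                                seed = 7)
  b <- sapply(ser, function(e) {
    s <- e$truth$brightnessScores
    if (length(s)) unname(s["epidermal"]) else 0
  })
  expect_gt(b[1], b[2])
  expect_gt(b[2], 0)
  expect_equal(b[3], 0)
  expect_equal(sapply(ser, `[[`, "dilutionIndex"), 1:3)
  # titer below the first dilution: everything negative
  serNeg <- generateDilutionSeries(base, titerIndex = 1L, nDilutions = 3L,
                                   seed = 7)
  expect_true(all(sapply(serNeg, function(e)
    length(e$truth$patternLabels) == 0L)))
  # single dilution: positive iff endpoint above it
  one <- generateDilutionSeries(base, titerIndex = 2L, nDilutions = 1L,
                                seed = 7)
  expect_identical(one[[1]]$truth$patternLabels, "epidermal")
  # reproducible per element
  ser2 <- generateDilutionSeries(base, titerIndex = 3L, nDilutions = 3L,
                                 seed = 7)
  expect_identical(pixels(ser[[2]]$image), pixels(ser2[[2]]$image))
})

test_that("generateDataset writes images, masks and a consistent manifest", {
  td <- withr::local_tempdir()
  cfg <- list(substrate = "split_skin",
              counts = c(epidermal = 3L, dermal = 2L, none = 4L),
              size = c(256L, 256L))
  man <- generateDataset(cfg, td, seed = 3)
  expect_equal(nrow(man), 9L)
  expect_equal(as.integer(table(man$pattern)[c("dermal", "epidermal",
                                               "none")]),
               c(2L, 3L, 4L))
  expect_true(all(file.exists(man$image_path)))
  expect_true(all(file.exists(man$mask_path)))
  m1 <- readMask(man$mask_path[1])
  expect_true(all(m1 %in% substrateClasses("split_skin")))
  # empty config: empty manifest, no images
  td2 <- withr::local_tempdir()
  man0 <- generateDataset(list(substrate = "split_skin",
                               counts = integer(0)), td2)
  expect_equal(nrow(man0), 0L)
  expect_length(list.files(td2, pattern = "png$"), 0L)
  # rerun determinism
  td3 <- withr::local_tempdir()
  man2 <- generateDataset(cfg, td3, seed = 3)
  expect_identical(readBin(man$image_path[1], "raw", 1e6),
                   readBin(man2$image_path[1], "raw", 1e6))
})
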