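tinyScenes <- function(n = 2L, substrate = "split_skin", seed = 17L) {
  cachedScene(paste0("tiny-", substrate, "-", n, "-", seed), {
    counts <- if (substrate == "split_skin")
      c(epidermal = ceiling(n / 2), none = floor(n / 2))
    else c(BMZ = ceiling(n / 2), none = floor(n / 2))
    generateScenes(substrate, counts, size = c(256L, 256L), seed = seed)
  })
}

test_that("generalized Dice loss reproduces its closed-form anchor cases", {
  # perfect prediction
  r <- cbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 1, 1))
  expect_equal(generalizedDiceLoss(r, r), 0)
  # uniform prediction on balanced two-class masks: 0.5 for any N
  for (N in c(4L, 20L, 256L)) {
    rb <- cbind(rep(c(1, 0), each = N / 2), rep(c(0, 1), each = N / 2))
    expect_equal(generalizedDiceLoss(matrix(0.5, N, 2), rb), 0.5)
  }
  # complementary binary prediction: total miss
  expect_equal(generalizedDiceLoss(1 - r, r), 1)
})

test_that("generalized Dice loss is permutation invariant and class-size robust", {
  set.seed(3)
  p <- matrix(runif(60), 20, 3); p <- p / rowSums(p)
  lab <- sample(1:3, 20, TRUE)
  r <- diag(3)[lab, ]
  perm <- c(3, 1, 2)
  expect_equal(generalizedDiceLoss(p[, perm], r[, perm]),
               generalizedDiceLoss(p, r))
  # robustness to imbalanced region sizes, in the two forms that hold
  # exactly: (a) rescaling every class by the same factor leaves GDL
  # unchanged (only per-class ratios matter); (b) completely missing a tiny
  # class costs about as much as completely missing a huge one
  mk <- function(n1, n2) {
    r2 <- rbind(matrix(rep(c(1, 0), n1), ncol = 2, byrow = TRUE),
                matrix(rep(c(0, 1), n2), ncol = 2, byrow = TRUE))
    p2 <- rbind(matrix(rep(c(0.8, 0.2), n1), ncol = 2, byrow = TRUE),
                matrix(rep(c(0.3, 0.7), n2), ncol = 2, byrow = TRUE))
    generalizedDiceLoss(p2, r2)
  }
  expect_lt(abs(mk(40L, 1000L) - mk(400L, 10000L)), 1e-9)
  missClass <- function(sizes, missed) {
    r2 <- rbind(matrix(rep(c(1, 0), sizes[1]), ncol = 2, byrow = TRUE),
                matrix(rep(c(0, 1), sizes[2]), ncol = 2, byrow = TRUE))
    p2 <- r2
    p2[r2[, missed] == 1, ] <- matrix(rep(if (missed == 1L) c(0, 1)
                                          else c(1, 0), sizes[missed]),
                                      ncol = 2, byrow = TRUE)
    generalizedDiceLoss(p2, r2)
  }
  a <- missClass(c(10L, 1000L), 1L)   # tiny class fully missed
  b <- missClass(c(10L, 1000L), 2L)   # huge class fully missed
  expect_gt(a, 0.9); expect_gt(b, 0.9)
  expect_lt(abs(a - b), 0.05)
})

test_that("analytic network gradients match finite differences", {
  set.seed(2)
  H <- 8L; W <- 8L; K <- 3L
  p <- unetInit(1L, K, 4L)
  p$head <- denseParam(4L, K)   # non-zero head so gradient flows everywhere
  x <- matrix(runif(H * W), H * W, 1L)
  oh <- onehotMask(matrix(sample(0:(K - 1), H * W, TRUE), H, W), K)
  lossOf <- function(p) {
    probs <- softmaxRows(unetForward(p, x, H, W)$logits)
    gdlParts(probs, oh)$loss
  }
  cache <- unetForward(p, x, H, W)
  probs <- softmaxRows(cache$logits)
  lg <- gdlWithGrad(probs, oh)
  grads <- unetBackward(p, cache, softmaxChain(probs, lg$dp))
  eps <- 1e-6
  for (nm in c("e1a", "e3b", "d1")) {
    for (k in c(2L, 5L)) {
      v <- p[[nm]]$W[[k]]
      i <- which.max(abs(grads[[nm]]$W[[k]]))   # probe the largest entry
      p1 <- p; p1[[nm]]$W[[k]][i] <- v[i] + eps
      p2 <- p; p2[[nm]]$W[[k]][i] <- v[i] - eps
      num <- (lossOf(p1) - lossOf(p2)) / (2 * eps)
      expect_equal(grads[[nm]]$W[[k]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("an untrained model outputs the uniform distribution", {
  cfg <- segConfig("split_skin", segSize = 16L, channels = 4L, seed = 3)
  m <- untrainedSegmenter(cfg)
  seg <- segmentImage(m, matrix(0, 64, 64))
  expect_true(all(abs(classProbs(seg) - 0.25) < 1e-12))
  # probabilities always sum to 1, also for arbitrary input
  seg2 <- segmentImage(m, matrix(runif(64 * 64), 64, 64))
  s <- apply(classProbs(seg2), c(1, 2), sum)
  expect_lt(max(abs(s - 1)), 1e-5)
  expect_true(validObject(seg2))
})

test_that("training is reproducible and learns a repeated image", {
  sc <- tinyScenes(2L)
  cfg <- segConfig("split_skin", segSize = 16L, channels = 4L, epochs = 3L,
                   seed = 9, augment = FALSE)
  m1 <- trainSegmenter(sc, cfg)
  m2 <- trainSegmenter(sc, cfg)
  expect_identical(m1$params, m2$params)
  # memorising copies of one image: loss decreases epoch over epoch
  rep4 <- rep(sc[1], 4L)
  cfg2 <- segConfig("split_skin", segSize = 16L, channels = 4L,
                    epochs = 6L, seed = 9, augment = FALSE)
  m3 <- trainSegmenter(rep4, cfg2)
  sm <- stats::filter(m3$curve, rep(1 / 2, 2), sides = 1)
  expect_lt(m3$curve[length(m3$curve)], m3$curve[1])
  expect_true(all(diff(sm[!is.na(sm)]) < 0.05))  # non-increasing trend
  expect_error(trainSegmenter(list(), cfg), "empty")
})

test_that("flip augmentation leaves the loss of a flip-symmetric model unchanged", {
  set.seed(12)
  K <- 4L
  p <- unetInit(1L, K, 4L)
  p$head <- denseParam(4L, K)
  # symmetrise every 3x3 kernel across the column axis (dc -> -dc pairs
  # under the offset ordering used by the conv layers: 1..3 <-> 7..9)
  symmetrise <- function(cp) {
    for (k in 1:3) {
      avg1 <- (cp$W[[k]] + cp$W[[k + 6]]) / 2
      cp$W[[k]] <- avg1; cp$W[[k + 6]] <- avg1
    }
    cp
  }
  for (nm in setdiff(names(p), "head")) p[[nm]] <- symmetrise(p[[nm]])
  sc <- tinyScenes(1L)[[1]]
  img <- resizeTo(pixels(sc$image), c(32L, 32L))
  mask <- resizeTo(sc$truth$segMask, c(32L, 32L), "nearest")
  lossOf <- function(img, mask) {
    x <- matrix(as.vector(img), 1024L, 1L)
    probs <- softmaxRows(unetForward(p, x, 32L, 32L)$logits)
    generalizedDiceLoss(probs, onehotMask(mask, K))
  }
  flip <- function(m) m[, rev(seq_len(ncol(m)))]
  expect_equal(lossOf(flip(img), flip(mask)), lossOf(img, mask),
               tolerance = 1e-12)
})
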