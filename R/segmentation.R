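#' Segmentation model configuration
#'
#' @param substrate `"split_skin"` (4 classes) or `"esophagus"` (7 classes).
#' @param segSize working resolution (square); images and masks are resized
#'   to `segSize x segSize` on load. The full-scale pipeline uses 512.
#' @param channels trunk width of the encoder-decoder.
#' @param epochs training epochs.
#' @param lr ADAM learning rate.
#' @param loss `"dice_ce"` (default: generalized Dice plus class-rebalanced
#'   categorical cross-entropy, equally weighted), `"generalized_dice"`, or
#'   `"categorical_cross_entropy"`. At desk scale the pure generalized Dice
#'   loss trains poorly (its inverse-squared-area weights concentrate nearly
#'   all gradient on the rarest class, and its softmax-chained gradient
#'   vanishes once that class's probability collapses), and plain
#'   cross-entropy never recovers thin rare classes such as the esophageal
#'   BMZ; the default combines the Dice term's class balancing with an
#'   inverse-frequency-weighted cross-entropy anchor.
#' @param augment apply flip / quarter-turn rotation augmentation.
#' @param seed RNG seed; training is reproducible given the seed.
#' @return classed list `segConfig`.
#' @export
segConfig <- function(substrate = c("split_skin", "esophagus"),
                      segSize = 512L, channels = 8L, epochs = 10L,
                      lr = 4e-3, loss = NULL, augment = TRUE, seed = 1L) {
  substrate <- match.arg(substrate)
  if (is.null(loss)) loss <- "dice_ce"
  loss <- match.arg(loss, c("dice_ce", "generalized_dice",
                            "categorical_cross_entropy"))
  stopifnot(segSize %% 4L == 0L, segSize >= 16L)
  structure(list(substrate = substrate, segSize = as.integer(segSize),
                 channels = as.integer(channels), epochs = as.integer(epochs),
                 lr = lr, loss = loss, augment = augment,
                 seed = as.integer(seed)),
            class = "segConfig")
}

# one-hot encode an integer label matrix (labels 0..K-1) to N x K
onehotMask <- function(mask, nClasses) {
  n <- length(mask)
  oh <- matrix(0, n, nClasses)
  oh[cbind(seq_len(n), as.vector(mask) + 1L)] <- 1
  oh
}

# flips and quarter-turn rotations applied identically to image and mask
augmentPair <- function(img, mask) {
  if (stats::runif(1) < 0.5) { img <- img[, rev(seq_len(ncol(img)))]
                               mask <- mask[, rev(seq_len(ncol(mask)))] }
  if (stats::runif(1) < 0.5) { img <- img[rev(seq_len(nrow(img))), ]
                               mask <- mask[rev(seq_len(nrow(mask))), ] }
  k <- sample(0:3, 1L)
  rot90 <- function(m, k) { for (i in seq_len(k)) m <- t(m[rev(seq_len(nrow(m))), ]); m }
  if (k > 0) { img <- rot90(img, k); mask <- rot90(mask, k) }
  list(img = img, mask = mask)
}

# normalise training input: list of scenes (from generateScenes) or a
# manifest data.frame with image_path / mask_path columns
loadTrainingPairs <- function(data, segSize) {
  if (is.data.frame(data)) {
    if (nrow(data) == 0L) stop("empty training manifest")
    lapply(seq_len(nrow(data)), function(i) {
      img <- pixels(loadGreen(data$image_path[i]))
      mask <- readMask(data$mask_path[i])
      list(img = resizeTo(img, c(segSize, segSize), "bilinear"),
           mask = resizeTo(mask, c(segSize, segSize), "nearest"))
    })
  } else {
    if (length(data) == 0L) stop("empty training set")
    lapply(data, function(sc) list(
      img = resizeTo(pixels(sc$image), c(segSize, segSize), "bilinear"),
      mask = resizeTo(sc$truth$segMask, c(segSize, segSize), "nearest")))
  }
}

#' Train the tissue segmenter
#'
#' Fits the scaled-down encoder-decoder (three resolution levels, summation
#' skip connections) with ADAM on image/mask pairs resized to the working
#' resolution. Split-skin training uses the generalized Dice loss for its
#' robustness to imbalanced region sizes; esophagus training uses
#' categorical cross-entropy. Flip and quarter-turn rotations augment each
#' presentation when `config$augment` is `TRUE`.
#'
#' @param data list of scenes (as from [generateScenes()]) or a manifest
#'   `data.frame` with `image_path` / `mask_path` columns.
#' @param config a [segConfig()].
#' @return a `segModel` (classed list) with the fitted parameters, the
#'   class table and the per-epoch training-loss curve.
#' @export
trainSegmenter <- function(data, config) {
  stopifnot(inherits(config, "segConfig"))
  classes <- names(substrateClasses(config$substrate))
  K <- length(classes)
  pairs <- loadTrainingPairs(data, config$segSize)
  bad <- vapply(pairs, function(p) max(p$mask) >= K, logical(1))
  if (any(bad)) stop("mask labels exceed the substrate class count")
  set.seed(config$seed)
  params <- unetInit(1L, K, config$channels)
  state <- adamInit(params)
  S <- config$segSize
  curve <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(seq_along(pairs))
    tot <- 0
    for (i in ord) {
      pr <- pairs[[i]]
      if (config$augment) {
        au <- augmentPair(pr$img, pr$mask)
        pr <- list(img = au$img, mask = au$mask)
      }
      x <- matrix(as.vector(pr$img), S * S, 1L)
      oh <- onehotMask(pr$mask, K)
      cache <- unetForward(params, x, S, S)
      probs <- softmaxRows(cache$logits)
      if (config$loss == "generalized_dice") {
        lg <- gdlWithGrad(probs, oh)
        dlogits <- softmaxChain(probs, lg$dp)
        loss <- lg$loss
      } else if (config$loss == "categorical_cross_entropy") {
        ce <- crossEntropyWithGrad(probs, oh)
        dlogits <- ce$dlogits
        loss <- ce$loss
      } else {                       # dice_ce, equally weighted; the CE
        lg <- gdlWithGrad(probs, oh)   # term is class-rebalanced because the
        ce <- crossEntropyWithGrad(probs, oh,          # softmax-chained Dice
                                   invFreqWeights(oh)) # gradient vanishes for
        dlogits <- softmaxChain(probs, lg$dp) + ce$dlogits  # collapsed rare
        loss <- lg$loss + ce$loss                           # classes
      }
      grads <- unetBackward(params, cache, dlogits)
      st <- adamStep(params, grads, state, lr = config$lr)
      params <- st$params; state <- st$state
      tot <- tot + loss
    }
    curve[ep] <- tot / length(pairs)
  }
  structure(list(params = params, classes = classes,
                 substrate = config$substrate, segSize = config$segSize,
                 config = config, curve = curve),
            class = "segModel")
}

#' @export
print.segModel <- function(x, ...) {
  cat(sprintf("segModel (%s): %d classes @ %d px, %d epochs, final loss %.4f\n",
              x$substrate, length(x$classes), x$segSize,
              length(x$curve), utils::tail(x$curve, 1)))
  invisible(x)
}

#' Segment an image
#'
#' Resizes the green-channel raster to the model's working resolution and
#' returns per-pixel class probabilities and the argmax label map.
#'
#' @param model a `segModel` from [trainSegmenter()] (or [untrainedSegmenter()]).
#' @param image an [IIFImage-class] or numeric matrix.
#' @return a [SegmentationResult-class].
#' @export
segmentImage <- function(model, image) {
  stopifnot(inherits(model, "segModel"))
  m <- if (is(image, "IIFImage")) pixels(image) else image
  S <- model$segSize
  m <- resizeTo(m, c(S, S), "bilinear")
  x <- matrix(as.vector(m), S * S, 1L)
  cache <- unetForward(model$params, x, S, S)
  probs <- softmaxRows(cache$logits)
  K <- length(model$classes)
  cm <- matrix(max.col(probs, ties.method = "first"), S, S)
  storage.mode(cm) <- "integer"
  new("SegmentationResult",
      classProbs = array(probs, c(S, S, K)),
      classMap = cm, classes = model$classes, substrate = model$substrate)
}

#' Untrained segmenter
#'
#' A freshly initialised model (zero-weight head), useful as a baseline:
#' its output is the uniform distribution over classes at every pixel.
#'
#' @inheritParams trainSegmenter
#' @return a `segModel`.
#' @export
untrainedSegmenter <- function(config) {
  stopifnot(inherits(config, "segConfig"))
  classes <- names(substrateClasses(config$substrate))
  set.seed(config$seed)
  structure(list(params = unetInit(1L, length(classes), config$channels),
                 classes = classes, substrate = config$substrate,
                 segSize = config$segSize, config = config,
                 curve = numeric(0)),
            class = "segModel")
}

#' Wrap a ground-truth mask as a SegmentationResult
#'
#' One-hot "segmentation" built from a reference mask, at the mask's own
#' resolution or resized (nearest neighbour) to `segSize`. Used to drive
#' the downstream geometry operations from exact ground truth.
#'
#' @param mask integer label matrix (labels per [substrateClasses()]).
#' @param substrate substrate name.
#' @param segSize optional working size; defaults to the mask's size.
#' @return a [SegmentationResult-class].
#' @export
truthSegmentation <- function(mask, substrate, segSize = NULL) {
  if (!is.null(segSize))
    mask <- resizeTo(mask, c(segSize, segSize), "nearest")
  classes <- names(substrateClasses(substrate))
  K <- length(classes)
  oh <- onehotMask(mask, K)
  cm <- mask + 1L
  storage.mode(cm) <- "integer"
  new("SegmentationResult",
      classProbs = array(oh, c(dim(mask), K)),
      classMap = cm, classes = classes, substrate = substrate)
}

#' Mean foreground Dice overlap
#'
#' Mean of the per-class Dice coefficients `2|A n B| / (|A| + |B|)` over the
#' non-background classes present in the reference mask.
#'
#' @param seg a [SegmentationResult-class].
#' @param truthMask integer reference mask (resized to the segmentation's
#'   working size with nearest neighbour if needed).
#' @return numeric in \[0, 1\].
#' @export
segmentationDice <- function(seg, truthMask) {
  cm <- classMap(seg)
  truthMask <- resizeTo(truthMask, dim(cm), "nearest")
  ref <- truthMask + 1L
  present <- setdiff(sort(unique(as.vector(ref))), 1L)  # skip background
  d <- vapply(present, function(k) {
    a <- cm == k; b <- ref == k
    2 * sum(a & b) / max(sum(a) + sum(b), 1L)
  }, numeric(1))
  mean(d)
}
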