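#' Compute attention lines from a split-skin segmentation
#'
#' The diagnostic fluorescence sits along the artificial split, so the
#' pipeline restricts analysis to two thin pixel sets computed by dilation
#' algebra on the segmented regions (roof `R`, floor `F`, interspace `I`):
#' `L_roof = DIL(R) & (DIL(F) | DIL(I))` and
#' `L_floor = DIL(F) & (DIL(R) | DIL(I))`,
#' with `DIL` the disc dilation of [dilateDisc()] (diameter 3 by default).
#'
#' @param seg a 4-class split-skin [SegmentationResult-class].
#' @param diameterPx dilation disc diameter.
#' @param scaleFactor factor mapping line coordinates to the classification
#'   raster (4 between the default 512 segmentation and 2048 raster).
#' @return an [AttentionLines-class].
#' @export
computeAttentionLines <- function(seg, diameterPx = 3L, scaleFactor = 4) {
  stopifnot(is(seg, "SegmentationResult"))
  if (seg@substrate != "split_skin")
    stop("attention lines are defined for the split-skin substrate")
  cm <- classMap(seg)
  cls <- classLabels(seg)
  R <- cm == which(cls == "roof")
  F_ <- cm == which(cls == "floor")
  I_ <- cm == which(cls == "interspace")
  dR <- dilateDisc(R, diameterPx)
  dF <- dilateDisc(F_, diameterPx)
  dI <- dilateDisc(I_, diameterPx)
  new("AttentionLines", roofLine = dR & (dF | dI),
      floorLine = dF & (dR | dI), scaleFactor = scaleFactor)
}

#' Line pixel coordinates at the classification raster
#'
#' Maps an attention line's pixel set from segmentation scale onto the
#' patch-sampling raster (pixel-centre mapping, rounded to the grid).
#'
#' @param lines an [AttentionLines-class].
#' @param side `"roof"` or `"floor"`.
#' @return integer matrix with columns `row`, `col` (1-based, raster scale).
#' @export
lineCoordinates <- function(lines, side = c("roof", "floor")) {
  side <- match.arg(side)
  mask <- if (side == "roof") roofLine(lines) else floorLine(lines)
  idx <- which(mask, arr.ind = TRUE)
  f <- lines@scaleFactor
  out <- round((idx - 0.5) * f + 0.5)
  storage.mode(out) <- "integer"
  colnames(out) <- c("row", "col")
  unique(out)
}

# polyline arc-length estimate of a (possibly thick) pixel line
lineArcLength <- function(coords) {
  if (nrow(coords) < 2L) return(nrow(coords))
  horiz <- diff(range(coords[, "col"])) >= diff(range(coords[, "row"]))
  a <- if (horiz) coords[, "col"] else coords[, "row"]
  b <- if (horiz) coords[, "row"] else coords[, "col"]
  mid <- tapply(b, a, mean)
  u <- as.numeric(names(mid))
  if (length(u) < 2L) return(nrow(coords))
  sum(sqrt(diff(u)^2 + diff(as.numeric(mid))^2))
}

#' Sample patches along an attention line by Poisson-disc sampling
#'
#' Draws up to `nTarget` patch centres from the line's pixels such that all
#' pairwise distances are at least the Poisson radius (a maximal random
#' sample is built by seeded dart throwing, then truncated to `nTarget`).
#' The fixed-count contract pads the list with `isPadding` patches (all-zero
#' pixels) when the line supports fewer centres; padding patches are later
#' scored 'background' and ignored by aggregation. Patches crossing the
#' image border are shifted inward to fit.
#'
#' @param image raster at the classification scale ([IIFImage-class] or
#'   matrix).
#' @param coords integer matrix of candidate centres (`row`, `col`) at the
#'   image's scale, e.g. from [lineCoordinates()].
#' @param nTarget fixed patch count (40 in the full-scale pipeline).
#' @param patchSize square patch side in pixels.
#' @param radius Poisson-disc radius; default is the line's arc length
#'   divided by `nTarget + 1`, clamped to \[8, 64\] px.
#' @param seed RNG seed for the dart-throwing order.
#' @return list of `nTarget` patches: `list(pixels, center, isPadding)`.
#' @export
samplePatches <- function(image, coords, nTarget = 40L, patchSize = 64L,
                          radius = NULL, seed = 1L) {
  m <- if (is(image, "IIFImage")) pixels(image) else image
  h <- nrow(m); w <- ncol(m)
  if (is.null(radius)) {
    len <- if (is.null(coords) || nrow(coords) == 0L) 0 else
      lineArcLength(coords)
    radius <- min(64, max(8, len / (nTarget + 1)))
  }
  centers <- NULL
  if (!is.null(coords) && nrow(coords) > 0L) {
    keep <- withSeed(seed, {
      ord <- sample.int(nrow(coords))
      acc <- integer(0)
      r2 <- radius^2
      for (i in ord) {
        if (length(acc)) {
          d2 <- (coords[acc, 1] - coords[i, 1])^2 +
                (coords[acc, 2] - coords[i, 2])^2
          if (min(d2) < r2) next
        }
        acc <- c(acc, i)
      }
      acc
    })
    centers <- coords[keep[seq_len(min(nTarget, length(keep)))], ,
                      drop = FALSE]
  }
  half <- patchSize %/% 2L
  out <- vector("list", nTarget)
  nReal <- if (is.null(centers)) 0L else nrow(centers)
  for (i in seq_len(nTarget)) {
    if (i <= nReal) {
      r0 <- min(max(centers[i, 1], half), h - patchSize + half)
      c0 <- min(max(centers[i, 2], half), w - patchSize + half)
      rows <- (r0 - half + 1L):(r0 - half + patchSize)
      colsx <- (c0 - half + 1L):(c0 - half + patchSize)
      out[[i]] <- list(pixels = m[rows, colsx],
                       center = c(row = unname(centers[i, 1]),
                                  col = unname(centers[i, 2])),
                       isPadding = FALSE)
    } else {
      out[[i]] <- list(pixels = matrix(0, patchSize, patchSize),
                       center = c(row = NA_integer_, col = NA_integer_),
                       isPadding = TRUE)
    }
  }
  attr(out, "radius") <- radius
  out
}

patchLabels <- c("positive", "negative", "background", "unclear")

#' Patch-network configuration
#'
#' @param channels trunk width.
#' @param hidden width of the two dense branches.
#' @param epochs,lr,seed training settings.
#' @param patchSize square patch side.
#' @param augment apply flip and Gaussian-noise augmentation to patches.
#' @param batch minibatch size (ADAM steps on mean batch gradients).
#' @param classWeight rebalance the label cross-entropy by inverse class
#'   frequency (capped), so sparse positive patches are not drowned out.
#' @return classed list `patchConfig`.
#' @export
patchConfig <- function(channels = 8L, hidden = 16L, epochs = 25L, lr = 2e-3,
                        seed = 1L, patchSize = 64L, augment = TRUE,
                        batch = 16L, classWeight = TRUE) {
  structure(list(channels = as.integer(channels), hidden = as.integer(hidden),
                 epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed), patchSize = as.integer(patchSize),
                 augment = augment, batch = as.integer(batch),
                 classWeight = classWeight, nStages = 4L),
            class = "patchConfig")
}

patchNetInit <- function(cfg) {
  p <- trunkInit(1L, cfg$channels, cfg$nStages)
  p$lab1 <- denseParam(3L * cfg$channels, cfg$hidden)
  p$lab2 <- denseParam(cfg$hidden, 4L, zero = TRUE)
  p$br1 <- denseParam(3L * cfg$channels, cfg$hidden)
  p$br2 <- denseParam(cfg$hidden, 1L, zero = TRUE)
  p
}

# Gaussian weight map centred on the patch, at the trunk's coarse output
# resolution. Patch centres sit on the attention line, so the diagnostic
# band of this side lies at the patch centre while the opposite side's band
# is off-centre: a centre-weighted pooled statistic restores the position
# information that global mean/max pooling discards.
patchCenterWeights <- function(cfg) {
  s <- cfg$patchSize %/% 2L^cfg$nStages
  ctr <- (s + 1) / 2
  sigma <- s / 5
  w <- exp(-(outer((seq_len(s) - ctr)^2, (seq_len(s) - ctr)^2, "+")) /
             (2 * sigma^2))
  as.vector(w)
}

# batched forward over B stacked patches; X is (B*S*S) x 1
patchNetForwardB <- function(params, X, cfg, B) {
  tc <- trunkForwardB(params, X, cfg$patchSize, B, cfg$nStages,
                      patchCenterWeights(cfg))
  H1 <- reluFwd(sweep(tc$g %*% params$lab1$W, 2, params$lab1$b, "+"))
  logits <- sweep(H1 %*% params$lab2$W, 2, params$lab2$b, "+")
  probs <- softmaxRows(logits)
  H2 <- reluFwd(sweep(tc$g %*% params$br1$W, 2, params$br1$b, "+"))
  bright <- as.vector(H2 %*% params$br2$W) + params$br2$b + 3  # score midpoint
  list(trunk = tc, H1 = H1, H2 = H2, probs = probs, bright = bright)
}

# mean batch loss: (optionally class-weighted) CE on the label head plus MSE
# on the brightness head, masked where no target applies; grads included
patchNetBackwardB <- function(params, fw, labelIdx, brightTarget, cfg, B,
                              classWeights = NULL) {
  onehot <- matrix(0, B, 4L)
  onehot[cbind(seq_len(B), labelIdx)] <- 1
  wpix <- if (is.null(classWeights)) rep(1, B) else classWeights[labelIdx]
  dlogits <- wpix * (fw$probs - onehot) / B
  dH1 <- (dlogits %*% t(params$lab2$W)) * (fw$H1 > 0)
  g <- list(lab2 = list(W = crossprod(fw$H1, dlogits),
                        b = colSums(dlogits)),
            lab1 = list(W = crossprod(fw$trunk$g, dH1), b = colSums(dH1)))
  dG <- dH1 %*% t(params$lab1$W)
  mask <- !is.na(brightTarget)
  err <- ifelse(mask, fw$bright - ifelse(mask, brightTarget, 0), 0)
  dbright <- 2 * err / B
  dH2 <- outer(dbright, as.vector(params$br2$W)) * (fw$H2 > 0)
  g$br2 <- list(W = crossprod(fw$H2, matrix(dbright)), b = sum(dbright))
  g$br1 <- list(W = crossprod(fw$trunk$g, dH2), b = colSums(dH2))
  dG <- dG + dH2 %*% t(params$br1$W)
  gT <- trunkBackwardB(params, fw$trunk, dG, B, cfg$nStages)
  g <- c(gT, g)
  eps <- 1e-12
  ce <- -sum(wpix * log(fw$probs[cbind(seq_len(B), labelIdx)] + eps)) / B
  loss <- ce + sum(err^2) / B
  list(grads = g, loss = loss)
}

# single-patch wrappers (used by tests and kept for clarity)
patchNetForward <- function(params, px, cfg) {
  fw <- patchNetForwardB(params, matrix(as.vector(px), ncol = 1L), cfg, 1L)
  list(trunk = fw$trunk, probs = as.vector(fw$probs),
       bright = fw$bright[1L], fwB = fw)
}

patchNetBackward <- function(params, fw, labelIdx, brightTarget, cfg) {
  patchNetBackwardB(params, fw$fwB, labelIdx, brightTarget, cfg, 1L)
}

#' Build a labelled patch dataset from synthetic scenes
#'
#' Extracts training patches for one side (roof or floor) from scenes with
#' ground truth: line patches along the truth-derived attention line
#' (labelled 'positive' when the side's pattern is active, else
#' 'negative'), 'background' patches from outside the tissue plus one
#' all-zero padding patch, and 'unclear' patches from tissue interior away
#' from the split. Brightness targets are the scene scores for line
#' patches; 'background' patches carry no brightness target.
#'
#' @param scenes list from [generateScenes()].
#' @param side `"roof"` or `"floor"` ([buildPatchDataset()]); `sides` is a
#'   vector of both for [buildPatchDatasets()], which shares the expensive
#'   raster resizes between the sides.
#' @param segSize,clsSize working sizes (segmentation / patch raster).
#' @param nLine,nBackground,nUnclear patches per scene per role.
#' @param patchSize square patch side.
#' @param seed RNG seed.
#' @return [buildPatchDataset()]: list with `patches` (list of matrices),
#'   `labelIdx` (1..4 into positive/negative/background/unclear) and
#'   `bright` (targets, `NA` where unused). [buildPatchDatasets()]: a named
#'   list of such datasets, one per side.
#' @export
buildPatchDataset <- function(scenes, side = c("roof", "floor"),
                              segSize = 128L, clsSize = 512L,
                              nLine = 8L, nBackground = 2L, nUnclear = 2L,
                              patchSize = 64L, seed = 1L) {
  side <- match.arg(side)
  buildPatchDatasets(scenes, sides = side, segSize = segSize,
                     clsSize = clsSize, nLine = nLine,
                     nBackground = nBackground, nUnclear = nUnclear,
                     patchSize = patchSize, seed = seed)[[side]]
}

#' @rdname buildPatchDataset
#' @param sides character vector of sides to build in one pass.
#' @export
buildPatchDatasets <- function(scenes, sides = c("roof", "floor"),
                               segSize = 128L, clsSize = 512L,
                               nLine = 8L, nBackground = 2L, nUnclear = 2L,
                               patchSize = 64L, seed = 1L) {
  stopifnot(all(sides %in% c("roof", "floor")))
  acc <- lapply(sides, function(s)
    list(patches = list(), labelIdx = integer(0), bright = numeric(0)))
  names(acc) <- sides
  push <- function(s, px, li, bt) {
    a <- acc[[s]]
    a$patches[[length(a$patches) + 1L]] <- px
    a$labelIdx <- c(a$labelIdx, li)
    a$bright <- c(a$bright, bt)
    acc[[s]] <<- a
  }
  sideOff <- stats::setNames(seq_along(sides) * 1000L, sides)
  for (si in seq_along(scenes)) {
    sc <- scenes[[si]]
    seg <- truthSegmentation(sc$truth$segMask, "split_skin", segSize)
    img <- resizeTo(pixels(sc$image), c(clsSize, clsSize), "bilinear")
    lines <- computeAttentionLines(seg, scaleFactor = clsSize / segSize)
    maskS <- resizeTo(sc$truth$segMask, c(segSize, segSize), "nearest")
    half <- patchSize %/% 2L
    sfac0 <- clsSize / segSize
    margin <- ceiling(half / sfac0) + 1L
    # aux-patch centres are drawn on the segmentation-scale mask and mapped
    # to the raster: cheaper than materialising full-size label masks
    pickFrom <- function(s, regionS, n, li, bt) {
      keep <- regionS
      keep[c(seq_len(margin), segSize - seq_len(margin) + 1L), ] <- FALSE
      keep[, c(seq_len(margin), segSize - seq_len(margin) + 1L)] <- FALSE
      idx <- which(keep, arr.ind = TRUE)
      if (!nrow(idx)) return(invisible())
      sel <- withSeed(seed * 131L + si * 7L + li + sideOff[[s]], {
        idx[sample.int(nrow(idx), min(n, nrow(idx))), , drop = FALSE]
      })
      for (j in seq_len(nrow(sel))) {
        r0 <- min(max(round((sel[j, 1] - 0.5) * sfac0 + 0.5), half),
                  clsSize - patchSize + half)
        c0 <- min(max(round((sel[j, 2] - 0.5) * sfac0 + 0.5), half),
                  clsSize - patchSize + half)
        push(s, img[(r0 - half + 1L):(r0 - half + patchSize),
                    (c0 - half + 1L):(c0 - half + patchSize)], li, bt)
      }
    }
    # attached stretches of the split carry side-ambiguous staining: with a
    # pattern present, the single band straddles the boundary and cannot be
    # assigned to roof or floor locally, so such line patches are taught
    # 'unclear' (visual readers, too, take the side from gapped stretches)
    interSeg <- resizeTo((sc$truth$segMask == 3L) * 1L,
                         c(segSize, segSize), "nearest") == 1L
    anyPattern <- length(sc$truth$patternLabels) > 0L
    sfac <- clsSize / segSize
    attachedAt <- function(center) {
      rs <- max(1L, min(segSize, round(center[["row"]] / sfac)))
      cs <- max(1L, min(segSize, round(center[["col"]] / sfac)))
      !any(interSeg[max(1L, rs - 3L):min(segSize, rs + 3L),
                    max(1L, cs - 3L):min(segSize, cs + 3L)])
    }
    for (s in sides) {
      pattern <- if (s == "roof") "epidermal" else "dermal"
      coords <- lineCoordinates(lines, s)
      ps <- samplePatches(img, coords, nTarget = nLine,
                          patchSize = patchSize,
                          seed = seed + si + sideOff[[s]])
      positive <- pattern %in% sc$truth$patternLabels
      li <- if (positive) 1L else 2L
      bt <- if (positive) unname(sc$truth$brightnessScores[pattern]) else 1
      for (p in ps) {
        if (p$isPadding) push(s, p$pixels, 3L, NA_real_)
        else if (anyPattern && attachedAt(p$center))
          push(s, p$pixels, 4L, NA_real_)
        else push(s, p$pixels, li, bt)
      }
      pickFrom(s, maskS == 0L, nBackground, 3L, NA_real_)
      # interior patches away from the split teach 'unclear'
      lineDist <- dilateDisc(if (s == "roof") roofLine(lines) else
                               floorLine(lines), 9L)
      farTissue <- (maskS == 1L | maskS == 2L) & !lineDist
      pickFrom(s, farTissue, nUnclear, 4L, NA_real_)
      push(s, matrix(0, patchSize, patchSize), 3L, NA_real_)
    }
  }
  acc
}

#' Train a two-head patch network
#'
#' Small convolutional trunk with two dense branches: a four-way label head
#' (positive / negative / background / unclear, cross-entropy) and a
#' brightness regression head (mean squared error on the \[1, 5\] score),
#' weighted equally, optimised with ADAM. Separate networks are trained for
#' roof and floor. Augmentation flips patches and adds Gaussian noise.
#'
#' @param dataset from [buildPatchDataset()].
#' @param side `"roof"` or `"floor"` (stored on the model).
#' @param config a [patchConfig()].
#' @return a `patchModel` (classed list).
#' @export
trainPatchNet <- function(dataset, side = c("roof", "floor"),
                          config = patchConfig()) {
  side <- match.arg(side)
  stopifnot(inherits(config, "patchConfig"))
  n <- length(dataset$patches)
  if (n == 0L) stop("empty patch dataset")
  set.seed(config$seed)
  params <- patchNetInit(config)
  state <- adamInit(params)
  curve <- numeric(config$epochs)
  B0 <- config$batch
  cw <- if (config$classWeight) {
    freq <- tabulate(dataset$labelIdx, 4L)
    w <- pmin(n / (4 * pmax(freq, 1)), 5)
    w / mean(w[freq > 0])
  } else NULL
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = B0)) {
      take <- ord[start:min(start + B0 - 1L, n)]
      B <- length(take)
      mats <- lapply(take, function(i) {
        px <- dataset$patches[[i]]
        if (config$augment) {
          if (stats::runif(1) < 0.5) px <- px[, rev(seq_len(ncol(px)))]
          if (stats::runif(1) < 0.5) px <- px[rev(seq_len(nrow(px))), ]
          if (stats::runif(1) < 0.5)
            px <- px + matrix(stats::rnorm(length(px), 0, 0.01), nrow(px))
        }
        as.vector(px)
      })
      X <- matrix(unlist(mats), ncol = 1L)
      fw <- patchNetForwardB(params, X, config, B)
      bw <- patchNetBackwardB(params, fw, dataset$labelIdx[take],
                              dataset$bright[take], config, B,
                              classWeights = cw)
      st <- adamStep(params, bw$grads, state, lr = config$lr)
      params <- st$params; state <- st$state
      tot <- tot + bw$loss * B
    }
    curve[ep] <- tot / n
  }
  structure(list(params = params, side = side, config = config,
                 curve = curve),
            class = "patchModel")
}

#' @export
print.patchModel <- function(x, ...) {
  cat(sprintf("patchModel [%s]: %d epochs, final loss %.4f\n", x$side,
              length(x$curve), utils::tail(x$curve, 1)))
  invisible(x)
}

#' Classify patches
#'
#' Runs each patch through the two-head network. Padding patches are scored
#' like any other (training teaches the network to call them 'background',
#' so aggregation ignores them).
#'
#' @param model a `patchModel`.
#' @param patches list from [samplePatches()] (or of plain matrices).
#' @return data.frame with the four label probabilities, `brightness`,
#'   `label` (argmax) and `isPadding`.
#' @export
classifyPatches <- function(model, patches) {
  stopifnot(inherits(model, "patchModel"))
  B <- length(patches)
  if (B == 0L) return(NULL)
  X <- matrix(unlist(lapply(patches, function(p)
    as.vector(if (is.list(p)) p$pixels else p))), ncol = 1L)
  fw <- patchNetForwardB(model$params, X, model$config, B)
  data.frame(p_positive = fw$probs[, 1], p_negative = fw$probs[, 2],
             p_background = fw$probs[, 3], p_unclear = fw$probs[, 4],
             brightness = fw$bright,
             label = patchLabels[max.col(fw$probs, ties.method = "first")],
             isPadding = vapply(patches, function(p)
               if (is.list(p)) isTRUE(p$isPadding) else FALSE, logical(1)),
             stringsAsFactors = FALSE)
}

#' Aggregate patch results into a side result
#'
#' Implements the printed aggregation: with `N` the patches whose argmax
#' label is 'negative' and `P` those whose argmax is 'positive' (patches
#' called 'background' or 'unclear' are ignored and cannot influence the
#' result), `yNeg` and `yPos` are the mean argmax-label probabilities over
#' `N` and `P` (0 when the set is empty) and
#' `y = (1 + yPos - yNeg) / 2`. The brightness `b` is the mean brightness of
#' the up-to-three patches with the highest 'positive' probability; with no
#' positive patch `b` is `NA` and the side is reported negative regardless
#' of `y` (no titer can be derived without positives).
#'
#' @param results data.frame from [classifyPatches()].
#' @param side `"roof"` or `"floor"`.
#' @param threshold decision threshold on `y`; a side with positives and
#'   `y >= threshold` is called positive (ties go to positive).
#' @return a [SideResult-class].
#' @export
aggregatePatches <- function(results, side = c("roof", "floor"),
                             threshold = 0.5) {
  side <- match.arg(side)
  isPos <- results$label == "positive"
  isNeg <- results$label == "negative"
  yPos <- if (any(isPos)) mean(results$p_positive[isPos]) else 0
  yNeg <- if (any(isNeg)) mean(results$p_negative[isNeg]) else 0
  y <- (1 + yPos - yNeg) / 2
  nP <- sum(isPos)
  if (nP > 0L) {
    posRows <- results[isPos, , drop = FALSE]
    top <- posRows[order(-posRows$p_positive)[seq_len(min(3L, nP))], ]
    b <- mean(top$brightness)
  } else b <- NA_real_
  call <- if (nP > 0L && y >= threshold) "positive" else "negative"
  new("SideResult", side = side, y = y, yPos = yPos, yNeg = yNeg, b = b,
      nInformative = as.integer(sum(isPos) + sum(isNeg)), call = call)
}

#' Calibrate the decision threshold of one side on training scenes
#'
#' The operating point on the aggregation statistic `y` is a free parameter
#' of the pipeline. This helper picks it from labelled training scenes:
#' each scene is scored through the ground-truth segmentation (attention
#' line, Poisson-disc sampling, patch classification, aggregation) and the
#' threshold maximising balanced accuracy over the training `y` values is
#' returned (midpoint between the best-separating pair; 0.5 on degenerate
#' input). Calibration never sees held-out data.
#'
#' @param scenes labelled training scenes ([generateScenes()]).
#' @param model `patchModel` for the side.
#' @param side `"roof"` or `"floor"`.
#' @param segSize,clsSize working sizes.
#' @param nPatches fixed patch count per line.
#' @param seed sampling seed.
#' @param segModel optional split-skin `segModel`: when given, training
#'   scenes are scored through the predicted segmentation (matching
#'   deployment); otherwise through ground truth.
#' @return threshold in (0, 1).
#' @export
calibrateSideThreshold <- function(scenes, model, side = c("roof", "floor"),
                                   segSize = 128L, clsSize = 2048L,
                                   nPatches = 40L, seed = 1L,
                                   segModel = NULL) {
  side <- match.arg(side)
  models <- list(); models[[side]] <- model
  calibrateSSSThresholds(scenes, roofModel = models$roof,
                         floorModel = models$floor, segModel = segModel,
                         segSize = segSize, clsSize = clsSize,
                         nPatches = nPatches, seed = seed)[[side]]
}

#' @rdname calibrateSideThreshold
#' @param roofModel,floorModel `patchModel`s; either may be `NULL` to skip
#'   that side.
#' @export
calibrateSSSThresholds <- function(scenes, roofModel = NULL,
                                   floorModel = NULL, segModel = NULL,
                                   segSize = 128L, clsSize = 2048L,
                                   nPatches = 40L, seed = 1L) {
  sides <- c(roof = !is.null(roofModel), floor = !is.null(floorModel))
  ys <- matrix(NA_real_, length(scenes), 2L,
               dimnames = list(NULL, c("roof", "floor")))
  pos <- matrix(FALSE, length(scenes), 2L,
                dimnames = list(NULL, c("roof", "floor")))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    seg <- if (is.null(segModel))
      truthSegmentation(sc$truth$segMask, "split_skin", segSize)
    else segmentImage(segModel, sc$image)
    segScale <- nrow(classMap(seg))
    lines <- computeAttentionLines(seg, scaleFactor = clsSize / segScale)
    img <- resizeTo(pixels(sc$image), c(clsSize, clsSize), "bilinear")
    for (s in names(sides)[sides]) {
      model <- if (s == "roof") roofModel else floorModel
      coords <- lineCoordinates(lines, s)
      ps <- samplePatches(img, coords, nTarget = nPatches,
                          patchSize = model$config$patchSize,
                          seed = seed + i + if (s == "floor") 5000L else 0L)
      sr <- aggregatePatches(classifyPatches(model, ps), side = s)
      ys[i, s] <- aggregationScore(sr)
      pos[i, s] <- (if (s == "roof") "epidermal" else "dermal") %in%
        sc$truth$patternLabels
    }
  }
  pick <- function(y, p) {
    keep <- !is.na(y); y <- y[keep]; p <- p[keep]
    if (!length(y) || !any(p) || all(p)) return(0.5)
    cand <- sort(unique(y))
    mids <- c(0.5, (cand[-1] + cand[-length(cand)]) / 2)
    bal <- vapply(mids, function(th)
      (mean(y[p] >= th) + mean(y[!p] < th)) / 2, numeric(1))
    mids[which.max(bal)]
  }
  out <- c(roof = 0.5, floor = 0.5)
  for (s in names(sides)[sides]) out[[s]] <- pick(ys[, s], pos[, s])
  out
}

#' Classify one side of a split-skin image
#'
#' Composes the inference stages for one attention line: line extraction
#' from the segmentation, Poisson-disc patch sampling on the
#' classification raster, patch classification and aggregation.
#'
#' @param image [IIFImage-class] (any size).
#' @param seg a split-skin [SegmentationResult-class] of the same image.
#' @param model `patchModel` for the matching side.
#' @param side `"roof"` or `"floor"`.
#' @param clsSize classification raster size (2048 full scale).
#' @param nPatches fixed patch count.
#' @param threshold decision threshold on `y`.
#' @param seed sampling seed.
#' @return a [SideResult-class].
#' @export
classifySide <- function(image, seg, model, side = c("roof", "floor"),
                         clsSize = 2048L, nPatches = 40L, threshold = 0.5,
                         seed = 1L) {
  side <- match.arg(side)
  if (model$side != side) stop("model was trained for side ", model$side)
  segSize <- nrow(classMap(seg))
  lines <- computeAttentionLines(seg, scaleFactor = clsSize / segSize)
  img <- resizeTo(if (is(image, "IIFImage")) pixels(image) else image,
                  c(clsSize, clsSize), "bilinear")
  classifySideRaster(img, lines, model, side, nPatches, threshold, seed)
}

# internal: classify one side given the already-resized raster and lines
classifySideRaster <- function(img, lines, model, side, nPatches = 40L,
                               threshold = 0.5, seed = 1L) {
  coords <- lineCoordinates(lines, side)
  ps <- samplePatches(img, coords, nTarget = nPatches,
                      patchSize = model$config$patchSize, seed = seed)
  res <- classifyPatches(model, ps)
  aggregatePatches(res, side = side, threshold = threshold)
}

#' Full split-skin prediction
#'
#' Segments the image and classifies both sides of the split.
#'
#' @param image [IIFImage-class].
#' @param segModel split-skin `segModel`.
#' @param roofModel,floorModel `patchModel`s.
#' @param clsSize,nPatches,seed forwarded to [classifySide()].
#' @param threshold decision threshold(s) on `y`: a scalar, or a named
#'   vector with entries `roof` and `floor` (e.g. from
#'   [calibrateSideThreshold()]).
#' @return list with `roof` and `floor` [SideResult-class] objects and the
#'   derived `pattern` call (`none`/`epidermal`/`dermal`/`both`).
#' @export
predictSSS <- function(image, segModel, roofModel, floorModel,
                       clsSize = 2048L, nPatches = 40L, threshold = 0.5,
                       seed = 1L) {
  th <- if (length(threshold) == 1L)
    c(roof = unname(threshold), floor = unname(threshold))
  else threshold
  seg <- segmentImage(segModel, image)
  segSize <- nrow(classMap(seg))
  lines <- computeAttentionLines(seg, scaleFactor = clsSize / segSize)
  img <- resizeTo(if (is(image, "IIFImage")) pixels(image) else image,
                  c(clsSize, clsSize), "bilinear")
  roof <- classifySideRaster(img, lines, roofModel, "roof", nPatches,
                             th[["roof"]], seed)
  floor <- classifySideRaster(img, lines, floorModel, "floor", nPatches,
                              th[["floor"]], seed + 1L)
  pat <- c("epidermal", "dermal")[c(sideCall(roof) == "positive",
                                    sideCall(floor) == "positive")]
  pattern <- if (length(pat) == 2L) "both" else if (length(pat) == 1L) pat
             else "none"
  list(roof = roof, floor = floor, pattern = pattern)
}
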