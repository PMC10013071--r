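#' Extract the binary BMZ mask from an esophagus segmentation
#'
#' Drops all segmentation information except the epidermal basement
#' membrane zone and returns it as a binary mask, upscaled by nearest
#' neighbour to the classification raster where it serves as the attention
#' input of the dual-input classifier.
#'
#' @param seg a 7-class esophagus [SegmentationResult-class].
#' @param clsSize target raster size (2048 full scale); `NULL` keeps the
#'   segmentation resolution.
#' @return logical matrix.
#' @export
extractBMZMask <- function(seg, clsSize = NULL) {
  stopifnot(is(seg, "SegmentationResult"))
  if (seg@substrate != "esophagus")
    stop("BMZ extraction needs an esophagus segmentation")
  mask <- classMap(seg) == which(classLabels(seg) == "BMZ")
  if (!is.null(clsSize))
    mask <- resizeTo(mask * 1L, c(clsSize, clsSize), "nearest") == 1L
  mask
}

#' Desmosome region adjacent to the BMZ
#'
#' The intercellular (desmosomal) staining sits in the epithelium just
#' above the BMZ. The region is predicted from the segmentation by growing
#' the BMZ mask `bandPx` times with the 3x3 disc (iterated binary dilation,
#' i.e. a box-kernel convolution thresholded at each step) and intersecting
#' with the epithelium class; the BMZ itself is excluded because the
#' classes are disjoint.
#'
#' @param seg esophagus [SegmentationResult-class].
#' @param bandPx band width in pixels at segmentation scale (>= 1).
#' @return logical matrix at segmentation scale.
#' @export
desmosomeRegion <- function(seg, bandPx = 20L) {
  stopifnot(is(seg, "SegmentationResult"))
  if (bandPx < 1L) stop("bandPx must be >= 1")
  bmz <- classMap(seg) == which(classLabels(seg) == "BMZ")
  epi <- classMap(seg) == which(classLabels(seg) == "epithelium")
  grown <- bmz
  for (i in seq_len(bandPx)) grown <- dilateDisc(grown, 3L)
  grown & epi
}

#' Quantile intensity of a region
#'
#' The pattern fluorescence appears as the brightest part of its region, so
#' its strength is read off as an upper quantile of the pixel intensities
#' inside the region (type-7 quantile interpolation). The raw intensity is
#' mapped onto the \[1, 5\] score scale by a piecewise-linear calibration;
#' the default maps raw 0 to score 1 and raw 1 to score 5, linearly.
#'
#' @param image [IIFImage-class] or matrix at the region's scale.
#' @param region logical matrix (non-empty).
#' @param q quantile in (0, 1); default 0.95.
#' @param calibration list with numeric vectors `raw` and `score` giving
#'   the calibration knots.
#' @return a [RegionIntensity-class].
#' @export
regionIntensity <- function(image, region, q = 0.95,
                            calibration = list(raw = c(0, 1),
                                               score = c(1, 5))) {
  m <- if (is(image, "IIFImage")) pixels(image) else image
  stopifnot(identical(dim(m), dim(region)))
  vals <- m[region]
  if (!length(vals)) stop("region is empty; no intensity can be extracted")
  raw <- unname(stats::quantile(vals, q, type = 7))
  score <- stats::approx(calibration$raw, calibration$score, xout = raw,
                         rule = 2)$y
  new("RegionIntensity", rawIntensity = raw, score = score,
      quantileUsed = q, regionSize = as.integer(sum(region)))
}

#' Esophagus classifier configuration
#'
#' @param channels trunk width.
#' @param hidden dense layer width.
#' @param netSize internal square input size of the classifier (the raster
#'   pair is downsampled to this before the trunk).
#' @param epochs,lr,seed training settings.
#' @param augment apply flip / quarter-turn augmentation to the input pair.
#' @return classed list `esoConfig`.
#' @export
esoConfig <- function(channels = 8L, hidden = 16L, netSize = 128L,
                      epochs = 8L, lr = 2e-3, seed = 1L, augment = TRUE) {
  stopifnot(netSize %% 16L == 0L)
  structure(list(channels = as.integer(channels), hidden = as.integer(hidden),
                 netSize = as.integer(netSize), epochs = as.integer(epochs),
                 lr = lr, seed = as.integer(seed), augment = augment,
                 nStages = 4L),
            class = "esoConfig")
}

esoNetInit <- function(cfg) {
  p <- trunkInit(2L, cfg$channels, cfg$nStages)
  p$h <- denseParam(4L * cfg$channels, cfg$hidden)
  p$head <- denseParam(cfg$hidden, 2L, zero = TRUE)
  p
}

esoNetForward <- function(params, img, mask, cfg) {
  S <- cfg$netSize
  x <- cbind(as.vector(img), as.vector(mask))
  # the binary BMZ mask acts as the attention input twice over: besides
  # feeding the trunk, it weights two extra pooled feature sets — one on
  # the BMZ band itself (linear BMZ staining) and one on the desmosome zone
  # grown from it into the epithelium (intercellular staining)
  band <- dilateDisc(mask > 0.5, 3L)
  zone <- band
  for (i in 1:6) zone <- dilateDisc(zone, 3L)
  zone <- zone & !band
  downTo <- function(m) {
    w <- matrix(as.numeric(m), S * S, 1L)
    h <- S
    for (s in seq_len(cfg$nStages)) {    # block-mean down to the coarse map
      w <- poolFwd(w, h, h)
      h <- h %/% 2L
    }
    as.vector(w)
  }
  tc <- trunkForward(params, x, S, S, cfg$nStages,
                     poolWeights = list(downTo(band), downTo(zone)))
  h <- reluFwd(denseFwd(tc$g, params$h))
  logits <- denseFwd(h, params$head)
  list(trunk = tc, h = h, logits = logits, probs = sigmoid(logits))
}

esoNetBackward <- function(params, fw, targets, cfg) {
  dlogits <- fw$probs - targets            # BCE through the sigmoids
  hd <- denseBwd(fw$h, params$head, dlogits)
  dh <- hd$dg * (fw$h > 0)
  h1 <- denseBwd(fw$trunk$g, params$h, dh)
  g <- trunkBackward(params, fw$trunk, h1$dg, cfg$nStages)
  g$h <- h1$grad; g$head <- hd$grad
  eps <- 1e-12
  loss <- -sum(targets * log(fw$probs + eps) +
               (1 - targets) * log(1 - fw$probs + eps))
  list(grads = g, loss = loss)
}

esoNetInputs <- function(image, bmzMask, cfg) {
  S <- cfg$netSize
  m <- if (is(image, "IIFImage")) pixels(image) else image
  img <- resizeTo(m, c(S, S), "bilinear")
  msk <- resizeTo(bmzMask * 1L, c(S, S), "nearest")
  list(img = img, mask = msk * 1)
}

#' Train the dual-input esophagus classifier
#'
#' Trains the attention classifier on image/BMZ-mask input pairs with
#' independent sigmoid heads for the 'BMZ' and 'intercellular' patterns
#' (binary cross-entropy, ADAM). The BMZ mask is produced on the fly by the
#' segmentation model (or taken from ground truth when `segModel` is
#' `NULL`), exactly as at inference time. 'negative' is the absence of both
#' calls, not a third head, so dual-positive sera are representable.
#'
#' @param scenes list from [generateScenes()] (esophagus).
#' @param segModel esophagus `segModel`, or `NULL` to use ground-truth
#'   masks.
#' @param config an [esoConfig()].
#' @return an `esoModel` (classed list).
#' @export
trainEsoClassifier <- function(scenes, segModel = NULL,
                               config = esoConfig()) {
  stopifnot(inherits(config, "esoConfig"))
  if (length(scenes) == 0L) stop("empty training set")
  pairs <- lapply(scenes, function(sc) {
    seg <- if (is.null(segModel))
      truthSegmentation(sc$truth$segMask, "esophagus")
    else segmentImage(segModel, sc$image)
    inp <- esoNetInputs(sc$image, extractBMZMask(seg), config)
    t <- c(BMZ = as.numeric("BMZ" %in% sc$truth$patternLabels),
           intercellular =
             as.numeric("intercellular" %in% sc$truth$patternLabels))
    list(img = inp$img, mask = inp$mask, targets = t)
  })
  set.seed(config$seed)
  params <- esoNetInit(config)
  state <- adamInit(params)
  curve <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(pairs))
    tot <- 0
    for (i in ord) {
      pr <- pairs[[i]]
      img <- pr$img; msk <- pr$mask
      if (config$augment) {
        if (stats::runif(1) < 0.5) { img <- img[, rev(seq_len(ncol(img)))]
                                     msk <- msk[, rev(seq_len(ncol(msk)))] }
        if (stats::runif(1) < 0.5) { img <- img[rev(seq_len(nrow(img))), ]
                                     msk <- msk[rev(seq_len(nrow(msk))), ] }
      }
      fw <- esoNetForward(params, img, msk, config)
      bw <- esoNetBackward(params, fw, pr$targets, config)
      st <- adamStep(params, bw$grads, state, lr = config$lr)
      params <- st$params; state <- st$state
      tot <- tot + bw$loss
    }
    curve[ep] <- tot / length(pairs)
  }
  structure(list(params = params, config = config, curve = curve),
            class = "esoModel")
}

#' @export
print.esoModel <- function(x, ...) {
  cat(sprintf("esoModel: %d epochs, final loss %.4f\n", length(x$curve),
              utils::tail(x$curve, 1)))
  invisible(x)
}

#' Classify an esophagus image
#'
#' Runs the dual-input classifier on the image and its binary BMZ attention
#' mask. Patterns with probability at or above their threshold are called.
#'
#' @param model an `esoModel`.
#' @param image [IIFImage-class] or matrix.
#' @param bmzMask logical BMZ mask (same scene; any scale).
#' @param thresholds named numeric thresholds per pattern.
#' @return an [EsoClassification-class].
#' @export
classifyEso <- function(model, image, bmzMask,
                        thresholds = c(BMZ = 0.5, intercellular = 0.5)) {
  stopifnot(inherits(model, "esoModel"))
  inp <- esoNetInputs(image, bmzMask, model$config)
  fw <- esoNetForward(model$params, inp$img, inp$mask, model$config)
  probs <- stats::setNames(as.numeric(fw$probs), c("BMZ", "intercellular"))
  calls <- names(probs)[probs >= thresholds[names(probs)]]
  new("EsoClassification", probs = probs, calls = calls,
      negative = length(calls) == 0L)
}

#' Calibrate per-pattern call thresholds on training scenes
#'
#' The sigmoid heads' operating points are free parameters; this picks
#' them from labelled training scenes by maximising balanced accuracy of
#' each head over the training probabilities (midpoint between the
#' best-separating pair, 0.5 on degenerate input). Calibration never sees
#' held-out data.
#'
#' @param scenes labelled training scenes.
#' @param segModel esophagus `segModel` (or `NULL` for ground-truth masks).
#' @param model an `esoModel`.
#' @return named numeric thresholds for `BMZ` and `intercellular`.
#' @export
calibrateEsoThresholds <- function(scenes, segModel, model) {
  pats <- c("BMZ", "intercellular")
  probs <- matrix(0, length(scenes), 2L, dimnames = list(NULL, pats))
  truth <- matrix(FALSE, length(scenes), 2L, dimnames = list(NULL, pats))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    seg <- if (is.null(segModel))
      truthSegmentation(sc$truth$segMask, "esophagus")
    else segmentImage(segModel, sc$image)
    cl <- classifyEso(model, sc$image, extractBMZMask(seg))
    probs[i, ] <- patternProbs(cl)[pats]
    truth[i, ] <- pats %in% sc$truth$patternLabels
  }
  th <- vapply(pats, function(p) {
    y <- probs[, p]; pos <- truth[, p]
    if (!any(pos) || all(pos)) return(0.5)
    cand <- sort(unique(y))
    mids <- c(0.5, (cand[-1] + cand[-length(cand)]) / 2)
    bal <- vapply(mids, function(t)
      (mean(y[pos] >= t) + mean(y[!pos] < t)) / 2, numeric(1))
    mids[which.max(bal)]
  }, numeric(1))
  stats::setNames(th, pats)
}

#' Full esophagus prediction
#'
#' Segments the image, extracts the BMZ attention mask, classifies the
#' patterns and, for each called pattern, extracts its region intensity
#' (BMZ class region for 'BMZ'; desmosome band for 'intercellular') as an
#' upper quantile mapped to the \[1, 5\] score.
#'
#' @param image [IIFImage-class].
#' @param segModel esophagus `segModel`.
#' @param esoModel an `esoModel`.
#' @param thresholds per-pattern call thresholds.
#' @param bandPx desmosome band width at segmentation scale.
#' @param q intensity quantile.
#' @return list with `classification` ([EsoClassification-class]) and
#'   `intensity` (named list of [RegionIntensity-class] per called
#'   pattern).
#' @export
predictEso <- function(image, segModel, esoModel,
                       thresholds = c(BMZ = 0.5, intercellular = 0.5),
                       bandPx = 10L, q = 0.95) {
  seg <- segmentImage(segModel, image)
  bmz <- extractBMZMask(seg)
  cls <- classifyEso(esoModel, image, bmz, thresholds)
  imgSeg <- resizeTo(if (is(image, "IIFImage")) pixels(image) else image,
                     dim(classMap(seg)), "bilinear")
  intensity <- list()
  for (pat in patternCalls(cls)) {
    region <- if (pat == "BMZ") bmz else desmosomeRegion(seg, bandPx)
    if (!any(region)) next
    intensity[[pat]] <- regionIntensity(imgSeg, region, q = q)
  }
  list(classification = cls, intensity = intensity, segmentation = seg)
}
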