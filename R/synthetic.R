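# Seeded synthetic IIF scenes with exact ground truth. The renderer is
# deliberately schematic: piecewise-constant tissue intensities, smooth random
# layer boundaries, linear fluorescence bands for the AIBD patterns, optional
# confounder staining and a Gaussian + shading noise model. It emulates the
# geometry and grading of real biochip images, not their texture.

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# low-frequency 1-D curve from the current RNG stream
smooth1d <- function(w, amp, ncomp = 3L) {
  x <- seq_len(w)
  out <- numeric(w)
  for (j in seq_len(ncomp)) {
    a <- stats::runif(1, 0.3, 1) * amp / ncomp * 2
    f <- stats::runif(1, 0.5, 2.5) * j
    ph <- stats::runif(1, 0, 2 * pi)
    out <- out + a * sin(2 * pi * f * x / w + ph)
  }
  out
}

# low-frequency 2-D field in [0, 1] from the current RNG stream
smoothField <- function(h, w, grid = 12L) {
  g <- matrix(stats::runif(grid * grid), grid, grid)
  f <- resizeTo(g, c(h, w), mode = "bilinear")
  rng <- range(f)
  if (diff(rng) < 1e-12) return(matrix(0.5, h, w))
  (f - rng[1]) / diff(rng)
}

#' Specify a synthetic IIF scene
#'
#' A `SceneSpec` fixes everything about a synthetic biochip image except the
#' nuisance randomness: substrate, active pattern(s) and their brightness,
#' confounder staining, tissue geometry seed, noise level and canvas size.
#' The same spec and seed always reproduce a byte-identical image.
#'
#' @param substrate `"split_skin"` or `"esophagus"`.
#' @param pattern `"none"`, `"both"`, or one of the substrate's patterns
#'   (split skin: `"epidermal"`, `"dermal"`; esophagus: `"BMZ"`,
#'   `"intercellular"`).
#' @param patternBrightness brightness in \[0, 1\] of each active pattern;
#'   scalar (recycled) or named vector. Must be positive for active
#'   patterns; inactive patterns have brightness 0 by construction.
#' @param confounder `"none"`, `"nuclear_speckle"` (bright nuclear dots in
#'   the epidermis/epithelium, always labelled negative) or
#'   `"diffuse_unspecific"`.
#' @param geometrySeed integer controlling the tissue geometry.
#' @param noiseSd standard deviation of additive Gaussian noise; 0 disables
#'   both noise and the multiplicative shading field.
#' @param size canvas `(h, w)`, each at least 256.
#' @param attachFrac fraction of the split-skin width where roof and floor
#'   are still attached (no interspace); linear fluorescence continues
#'   through attached stretches.
#' @return a `SceneSpec` (classed list).
#' @export
sceneSpec <- function(substrate = c("split_skin", "esophagus"),
                      pattern = "none", patternBrightness = 1,
                      confounder = c("none", "nuclear_speckle",
                                     "diffuse_unspecific"),
                      geometrySeed = 1L, noiseSd = 0.02,
                      size = c(1024L, 1024L), attachFrac = 0.3) {
  substrate <- match.arg(substrate)
  confounder <- match.arg(confounder)
  pats <- substratePatterns(substrate)
  if (!pattern %in% c("none", "both", pats))
    stop("pattern '", pattern, "' is not valid for substrate '", substrate,
         "'")
  active <- switch(pattern, none = character(0), both = pats, pattern)
  b <- stats::setNames(numeric(2), pats)
  if (length(active)) {
    if (is.null(names(patternBrightness))) {
      b[active] <- rep_len(patternBrightness, length(active))
    } else {
      miss <- setdiff(active, names(patternBrightness))
      if (length(miss)) stop("missing brightness for: ",
                             paste(miss, collapse = ", "))
      b[active] <- patternBrightness[active]
    }
    if (any(b[active] <= 0) || any(b[active] > 1))
      stop("active pattern brightness must lie in (0, 1]")
  }
  stopifnot(length(size) == 2L, all(size >= 256L), noiseSd >= 0,
            attachFrac >= 0, attachFrac <= 1)
  structure(list(substrate = substrate, pattern = pattern, active = active,
                 brightness = b, confounder = confounder,
                 geometrySeed = as.integer(geometrySeed),
                 noiseSd = noiseSd, size = as.integer(size),
                 attachFrac = attachFrac),
            class = "SceneSpec")
}

bandThickness <- function(h) max(2L, round(h / 170))

renderSplitSkin <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  geom <- withSeed(spec$geometrySeed, {
    ctr <- h * 0.5 + smooth1d(w, 0.06 * h)
    top <- h * 0.10 + smooth1d(w, 0.02 * h)
    bot <- h * 0.90 + smooth1d(w, 0.02 * h)
    g0 <- h * 0.020 * (0.6 + 0.4 * (0.5 + smooth1d(w, 0.5)))
    u <- 0.5 + smooth1d(w, 0.9, ncomp = 4L)
    u <- (u - min(u)) / max(diff(range(u)), 1e-9)
    list(ctr = ctr, top = top, bot = bot, g0 = pmax(g0, 0), u = u)
  })
  thr <- stats::quantile(geom$u, spec$attachFrac)
  gap <- geom$g0 * pmax(0, (geom$u - thr) / max(1 - thr, 1e-9))
  rows <- matrix(seq_len(h), h, w)
  C <- matrix(geom$ctr, h, w, byrow = TRUE)
  G <- matrix(gap, h, w, byrow = TRUE)
  Tt <- matrix(geom$top, h, w, byrow = TRUE)
  Bb <- matrix(geom$bot, h, w, byrow = TRUE)
  tissue <- rows >= Tt & rows <= Bb
  attached <- G <= 0.5
  roof <- tissue & ((!attached & rows < C - G) | (attached & rows <= C))
  floorM <- tissue & ((!attached & rows > C + G) | (attached & rows > C))
  inter <- tissue & !roof & !floorM
  lab <- matrix(0L, h, w)
  lab[roof] <- 1L; lab[floorM] <- 2L; lab[inter] <- 3L
  img <- matrix(0.03, h, w)
  img[roof] <- 0.32; img[floorM] <- 0.20; img[inter] <- 0.08
  hb <- bandThickness(h)
  bandRoof <- roof & rows > C - G - hb
  bandFloor <- floorM & rows <= C + G + hb
  if (spec$brightness[["epidermal"]] > 0)
    img[bandRoof] <- img[bandRoof] + 0.55 * spec$brightness[["epidermal"]]
  if (spec$brightness[["dermal"]] > 0)
    img[bandFloor] <- img[bandFloor] + 0.55 * spec$brightness[["dermal"]]
  list(img = img, lab = lab, bands = list(epidermal = bandRoof,
                                          dermal = bandFloor),
       hostMask = roof)   # epidermis hosts nuclear speckles
}

renderEsophagus <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  # the BMZ band spans ~2% of the tissue height so that it remains a few
  # pixels wide at the segmentation working scale, as in the full-scale
  # system where a ~25 px band survives the downscale to the working size
  bmzTh <- max(2L, round(h / 50))
  geom <- withSeed(spec$geometrySeed, {
    waves <- lapply(1:6, function(i) smooth1d(w, 0.02 * h))
    meshF <- smoothField(h, w, grid = max(8L, round(h / 24)))
    list(waves = waves, meshF = meshF)
  })
  # cumulative layer boundaries (top of each layer), per column
  depth <- c(0.06, 0.30, bmzTh / h, 0.12, 0.10, 0.16, 0.16)
  tops <- list()
  cur <- h * depth[1] + geom$waves[[1]]
  for (i in 1:6) {
    tops[[i]] <- cur
    cur <- cur + h * depth[i + 1] + if (i < 6) geom$waves[[i + 1]] * 0.3 else 0
  }
  bottom <- cur
  rows <- matrix(seq_len(h), h, w)
  Bnd <- function(v) matrix(v, h, w, byrow = TRUE)
  lab <- matrix(0L, h, w)
  cls <- substrateClasses("esophagus")
  layers <- c("epithelium", "BMZ", "lamina_propria", "muscular_mucosa",
              "circular_muscle", "longitudinal_muscle")
  for (i in seq_along(layers)) {
    lo <- Bnd(tops[[i]])
    hi <- if (i < 6) Bnd(tops[[i + 1]]) else Bnd(rep(bottom, length.out = w))
    lab[rows >= lo & rows < hi] <- cls[[layers[i]]]
  }
  base <- c(background = 0.03, epithelium = 0.30, BMZ = 0.10,
            lamina_propria = 0.20, muscular_mucosa = 0.40,
            circular_muscle = 0.15, longitudinal_muscle = 0.25)
  img <- matrix(base[["background"]], h, w)
  for (nm in layers) img[lab == cls[[nm]]] <- base[[nm]]
  bmzBand <- lab == cls[["BMZ"]]
  epi <- lab == cls[["epithelium"]]
  # contour-web mesh; the band half-width (0.05 in field units) keeps the
  # web lines a few pixels wide at the classifier's working scale, matching
  # how clearly the intercellular mesh reads at the full-scale input size
  mesh <- abs(geom$meshF - round(geom$meshF * 5) / 5) < 0.05
  meshBand <- epi & mesh
  if (spec$brightness[["BMZ"]] > 0)
    img[bmzBand] <- img[bmzBand] + 0.55 * spec$brightness[["BMZ"]]
  if (spec$brightness[["intercellular"]] > 0)
    img[meshBand] <- img[meshBand] + 0.50 * spec$brightness[["intercellular"]]
  list(img = img, lab = lab,
       bands = list(BMZ = bmzBand, intercellular = meshBand),
       hostMask = epi)
}

#' Generate a synthetic IIF image with ground truth
#'
#' Renders the scene described by a [sceneSpec()]: tissue geometry is drawn
#' from `geometrySeed`, while confounder placement, shading and pixel noise
#' are drawn from `seed`. Active patterns are rendered as linear
#' fluorescence bands whose contrast over the local tissue is proportional
#' to their brightness; the returned ground truth contains the label mask,
#' the active patterns and their brightness scores on the \[1, 5\] scale
#' (`score = 1 + 4 * brightness`).
#'
#' @param spec a `SceneSpec`.
#' @param seed integer nuisance seed.
#' @return list with elements `image` ([IIFImage-class]) and `truth` (list
#'   `segMask`, `patternLabels`, `brightnessScores`, `bands`).
#' @export
generateImage <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "SceneSpec"))
  sc <- if (spec$substrate == "split_skin") renderSplitSkin(spec)
        else renderEsophagus(spec)
  img <- withSeed(seed, {
    im <- sc$img
    h <- spec$size[1]; w <- spec$size[2]
    if (spec$confounder == "nuclear_speckle") {
      host <- which(sc$hostMask, arr.ind = TRUE)
      if (nrow(host)) {
        n <- max(10L, round(h * w / 16000))
        pick <- host[sample.int(nrow(host), min(n, nrow(host))), ,
                     drop = FALSE]
        rad <- 2L
        for (i in seq_len(nrow(pick))) {
          r0 <- pick[i, 1]; c0 <- pick[i, 2]
          rr <- max(1, r0 - rad):min(h, r0 + rad)
          cc <- max(1, c0 - rad):min(w, c0 + rad)
          d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
          im[rr, cc][d2 <= rad^2] <- im[rr, cc][d2 <= rad^2] + 0.35
        }
      }
    } else if (spec$confounder == "diffuse_unspecific") {
      im <- im + 0.12 * smoothField(h, w) * (sc$lab > 0)
    }
    if (spec$noiseSd > 0) {
      shading <- 1 + 0.10 * (smoothField(h, w, grid = 6L) - 0.5) * 2
      im <- im * shading + matrix(stats::rnorm(h * w, 0, spec$noiseSd), h, w)
    }
    im
  })
  scores <- stats::setNames(1 + 4 * spec$brightness[spec$active],
                            spec$active)
  list(image = IIFImage(img,
                        metadata = list(substrate = spec$substrate)),
       truth = list(segMask = sc$lab, patternLabels = spec$active,
                    brightnessScores = scores, bands = sc$bands))
}

#' Generate a synthetic dilution series
#'
#' Emulates incubating one serum at successive half-log dilutions: pattern
#' brightness decreases strictly with the dilution index and reaches 0 at
#' `titerIndex` (the endpoint: the first negative dilution). Each element is
#' reproducible from `(seed, dilutionIndex)`; geometry differs per dilution
#' because each dilution is a different biochip.
#'
#' @param baseSpec a `SceneSpec` giving the substrate, pattern and the
#'   brightness at the first dilution.
#' @param titerIndex integer >= 1; images at dilution index >= `titerIndex`
#'   are negative. `titerIndex = 1` makes the whole series negative.
#' @param nDilutions number of images in the series.
#' @param seed integer.
#' @return list of elements `list(image, truth, dilutionIndex)`.
#' @export
generateDilutionSeries <- function(baseSpec, titerIndex, nDilutions,
                                   seed = 1L) {
  stopifnot(inherits(baseSpec, "SceneSpec"), titerIndex >= 1L,
            nDilutions >= 1L)
  lapply(seq_len(nDilutions), function(d) {
    fade <- if (titerIndex <= 1L || d >= titerIndex) 0
            else (titerIndex - d) / (titerIndex - 1)
    b <- baseSpec$brightness * fade
    pat <- if (fade == 0 || baseSpec$pattern == "none") "none"
           else baseSpec$pattern
    sp <- sceneSpec(baseSpec$substrate, pattern = pat,
                    patternBrightness = if (pat == "none") 1 else
                      b[baseSpec$active],
                    confounder = baseSpec$confounder,
                    geometrySeed = baseSpec$geometrySeed + d,
                    noiseSd = baseSpec$noiseSd, size = baseSpec$size,
                    attachFrac = baseSpec$attachFrac)
    out <- generateImage(sp, seed = seed + d)
    out$dilutionIndex <- d
    out
  })
}

#' Generate a labelled synthetic scene collection
#'
#' In-memory workhorse behind [generateDataset()]: draws `counts[p]` scenes
#' per pattern (`"none"`, individual patterns, or `"both"`), with brightness
#' sampled uniformly in `brightnessRange` and a random confounder mix.
#'
#' @param substrate `"split_skin"` or `"esophagus"`.
#' @param counts named integer vector, e.g. `c(epidermal = 5, none = 7)`.
#' @param size canvas `(h, w)`.
#' @param noiseSd Gaussian noise sd.
#' @param brightnessRange length-2 range for active-pattern brightness.
#' @param confounderProb probability that a scene carries a confounder.
#' @param seed integer; scene `i` depends only on `(seed, i)`.
#' @return list of scenes as returned by [generateImage()], each with an
#'   added `$pattern` field.
#' @export
generateScenes <- function(substrate, counts, size = c(512L, 512L),
                           noiseSd = 0.02, brightnessRange = c(0.35, 1),
                           confounderProb = 0.3, seed = 1L) {
  pats <- c("none", substratePatterns(substrate), "both")
  stopifnot(all(names(counts) %in% pats))
  plan <- rep(names(counts), times = counts)
  out <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    prm <- withSeed(seed * 10000L + i, {
      list(b = stats::runif(2, brightnessRange[1], brightnessRange[2]),
           conf = if (stats::runif(1) < confounderProb)
             sample(c("nuclear_speckle", "diffuse_unspecific"), 1L)
           else "none")
    })
    sp <- sceneSpec(substrate, pattern = plan[i],
                    patternBrightness = if (plan[i] == "none") 1 else
                      prm$b[seq_len(if (plan[i] == "both") 2L else 1L)],
                    confounder = prm$conf,
                    geometrySeed = seed * 10000L + i,
                    noiseSd = noiseSd, size = size)
    sc <- generateImage(sp, seed = seed * 10000L + i + 1L)
    sc$pattern <- plan[i]
    out[[i]] <- sc
  }
  out
}

#' Write a synthetic dataset to disk
#'
#' Renders scenes with [generateScenes()] and writes them as grayscale
#' images (PNG by default) plus indexed-PNG label masks and a CSV manifest
#' with one row per image (`image_path, mask_path, substrate, pattern,
#' brightness, dilution_index, serum_id, seed`).
#'
#' @param config list with fields `substrate`, `counts`, and optionally
#'   `size`, `noiseSd`, `brightnessRange`, `confounderProb`, `format`
#'   (`"png"` or `"tiff"`).
#' @param outDir output directory (created if missing).
#' @param seed integer.
#' @return the manifest `data.frame`, invisibly; also written to
#'   `file.path(outDir, "manifest.csv")`.
#' @export
generateDataset <- function(config, outDir, seed = 1L) {
  stopifnot(is.list(config), !is.null(config$substrate))
  counts <- config$counts
  if (is.null(counts)) counts <- integer(0)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  manifest <- data.frame(image_path = character(0), mask_path = character(0),
                         substrate = character(0), pattern = character(0),
                         brightness = numeric(0), dilution_index = integer(0),
                         serum_id = character(0), seed = integer(0),
                         stringsAsFactors = FALSE)
  if (sum(counts) > 0) {
    scenes <- generateScenes(config$substrate, counts,
                             size = config$size %||% c(512L, 512L),
                             noiseSd = config$noiseSd %||% 0.02,
                             brightnessRange =
                               config$brightnessRange %||% c(0.35, 1),
                             confounderProb = config$confounderProb %||% 0.3,
                             seed = seed)
    ext <- if (identical(config$format, "tiff")) "tif" else "png"
    rows <- lapply(seq_along(scenes), function(i) {
      sc <- scenes[[i]]
      ip <- file.path(outDir, sprintf("img_%04d.%s", i, ext))
      mp <- file.path(outDir, sprintf("mask_%04d.png", i))
      writeGray(sc$image, ip)
      writeMask(sc$truth$segMask, mp)
      data.frame(image_path = ip, mask_path = mp,
                 substrate = config$substrate, pattern = sc$pattern,
                 brightness = if (length(sc$truth$brightnessScores))
                   mean(sc$truth$brightnessScores) else NA_real_,
                 dilution_index = NA_integer_,
                 serum_id = sprintf("S%04d", i), seed = seed,
                 stringsAsFactors = FALSE)
    })
    manifest <- do.call(rbind, rows)
  }
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
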