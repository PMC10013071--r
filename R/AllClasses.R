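#' @import methods
NULL

#' Single-channel fluorescence image
#'
#' Container for the green-channel raster of a biochip image. Pixels are a
#' numeric matrix in `[row, col]` orientation (origin top-left, 0-based
#' coordinates in all exported coordinate tables), normalised to `[0, 1]`.
#' Optional metadata carries serum id, substrate and dilution index.
#'
#' @slot pixels numeric matrix of intensities in \[0, 1\].
#' @slot metadata named list; recognised fields are `serumId`, `substrate`
#'   (`"split_skin"` or `"esophagus"`) and `dilutionIndex`.
#' @exportClass IIFImage
setClass("IIFImage",
  representation(pixels = "matrix", metadata = "list"),
  prototype(pixels = matrix(0, 1, 1), metadata = list())
)

setValidity("IIFImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (length(dim(p)) != 2L) return("pixels must be 2-D")
  rng <- range(p, finite = TRUE)
  if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
    return("pixel intensities must lie in [0, 1]")
  md <- object@metadata
  if (!is.null(md$substrate) &&
      !md$substrate %in% c("split_skin", "esophagus"))
    return("metadata$substrate must be 'split_skin' or 'esophagus'")
  TRUE
})

#' Per-pixel semantic segmentation result
#'
#' Holds class probabilities and the argmax label map at the segmentation
#' working resolution. For salt-split skin the class set is
#' `background, roof, floor, interspace`; for esophagus it is
#' `background, epithelium, BMZ, lamina_propria, muscular_mucosa,
#' circular_muscle, longitudinal_muscle`.
#'
#' @slot classProbs numeric array `h x w x k` of per-pixel class
#'   probabilities, each pixel summing to 1.
#' @slot classMap integer matrix of argmax class indices (1-based into
#'   `classes`).
#' @slot classes character vector of class names, in probability order.
#' @slot substrate `"split_skin"` or `"esophagus"`.
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(classProbs = "array", classMap = "matrix",
                 classes = "character", substrate = "character")
)

setValidity("SegmentationResult", function(object) {
  d <- dim(object@classProbs)
  if (length(d) != 3L) return("classProbs must be h x w x k")
  if (d[3] != length(object@classes))
    return("third dim of classProbs must match length(classes)")
  if (!identical(dim(object@classMap), d[1:2]))
    return("classMap shape must match classProbs")
  s <- rowSums(matrix(object@classProbs, prod(d[1:2]), d[3]))
  if (max(abs(s - 1)) > 1e-5)
    return("per-pixel probabilities must sum to 1 (within 1e-5)")
  if (min(object@classProbs) < -1e-8) return("probabilities must be >= 0")
  if (!object@substrate %in% c("split_skin", "esophagus"))
    return("substrate must be 'split_skin' or 'esophagus'")
  TRUE
})

#' Attention lines along the artificial split
#'
#' Pixel sets on the epidermal (roof) and dermal (floor) side of the split,
#' obtained by dilating the segmented roof/floor/interspace regions and
#' intersecting them. Stored as logical masks at the segmentation working
#' size together with the scale factor that maps their coordinates onto the
#' patch-sampling raster.
#'
#' @slot roofLine,floorLine logical matrices at segmentation scale.
#' @slot scaleFactor numeric; multiply (row, col) by this to reach the
#'   classification raster.
#' @exportClass AttentionLines
setClass("AttentionLines",
  representation(roofLine = "matrix", floorLine = "matrix",
                 scaleFactor = "numeric")
)

setValidity("AttentionLines", function(object) {
  if (!is.logical(object@roofLine) || !is.logical(object@floorLine))
    return("lines must be logical masks")
  if (!identical(dim(object@roofLine), dim(object@floorLine)))
    return("roof and floor masks must share a shape")
  if (object@scaleFactor <= 0) return("scaleFactor must be positive")
  TRUE
})

#' Aggregated per-side result for salt-split skin
#'
#' Summary of one attention line: the aggregation statistic
#' `y = (1 + yPos - yNeg) / 2`, its components, the brightness score `b`
#' (mean of the up-to-three patches with the highest 'positive' probability;
#' `NA` when no patch is called positive) and the final call.
#'
#' @slot side `"roof"` or `"floor"`.
#' @slot y,yPos,yNeg numeric in \[0, 1\].
#' @slot b numeric brightness score in score units (target range \[1, 5\]),
#'   `NA_real_` when undefined.
#' @slot nInformative integer count of patches whose argmax label was
#'   'positive' or 'negative'.
#' @slot call `"positive"` or `"negative"`.
#' @exportClass SideResult
setClass("SideResult",
  representation(side = "character", y = "numeric", yPos = "numeric",
                 yNeg = "numeric", b = "numeric", nInformative = "integer",
                 call = "character")
)

setValidity("SideResult", function(object) {
  if (!object@side %in% c("roof", "floor"))
    return("side must be 'roof' or 'floor'")
  if (object@y < -1e-9 || object@y > 1 + 1e-9) return("y must be in [0, 1]")
  if (abs(object@y - (1 + object@yPos - object@yNeg) / 2) > 1e-9)
    return("y must equal (1 + yPos - yNeg)/2")
  if (!object@call %in% c("positive", "negative"))
    return("call must be 'positive' or 'negative'")
  TRUE
})

#' Esophagus pattern classification
#'
#' Independent per-pattern probabilities for the 'BMZ' and 'intercellular'
#' patterns; `calls` holds the patterns at or above their thresholds and
#' `negative` is `TRUE` exactly when no pattern is called.
#'
#' @slot probs named numeric vector with entries `BMZ` and `intercellular`,
#'   each in \[0, 1\].
#' @slot calls character subset of `c("BMZ", "intercellular")`.
#' @slot negative logical.
#' @exportClass EsoClassification
setClass("EsoClassification",
  representation(probs = "numeric", calls = "character", negative = "logical")
)

setValidity("EsoClassification", function(object) {
  if (!all(c("BMZ", "intercellular") %in% names(object@probs)))
    return("probs must be named with 'BMZ' and 'intercellular'")
  if (any(object@probs < -1e-9) || any(object@probs > 1 + 1e-9))
    return("probabilities must lie in [0, 1]")
  if (!all(object@calls %in% c("BMZ", "intercellular")))
    return("calls must be a subset of {BMZ, intercellular}")
  if (!identical(object@negative, length(object@calls) == 0L))
    return("negative must hold iff calls is empty")
  TRUE
})

#' Quantile intensity of an image region
#'
#' @slot rawIntensity numeric in \[0, 1\]: the chosen quantile of pixel
#'   intensities inside the region.
#' @slot score numeric in \[1, 5\]: piecewise-linear calibration of
#'   `rawIntensity` onto score units.
#' @slot quantileUsed numeric in (0, 1).
#' @slot regionSize integer pixel count of the region.
#' @exportClass RegionIntensity
setClass("RegionIntensity",
  representation(rawIntensity = "numeric", score = "numeric",
                 quantileUsed = "numeric", regionSize = "integer")
)

setValidity("RegionIntensity", function(object) {
  if (object@quantileUsed <= 0 || object@quantileUsed >= 1)
    return("quantileUsed must be in (0, 1)")
  if (object@regionSize < 1L) return("region must be non-empty")
  TRUE
})

#' Estimated antibody titer
#'
#' @slot pattern the pattern the titer refers to.
#' @slot titer integer denominator from the canonical dilution series
#'   (10, 32, 100, 320, ...); `NA` for a negative serum.
#' @slot basis how the titer was obtained: from a single image, capped by
#'   the first negative dilution, or open-ended (no negative image in the
#'   series).
#' @exportClass TiterResult
setClass("TiterResult",
  representation(pattern = "character", titer = "numeric", basis = "character")
)

setValidity("TiterResult", function(object) {
  if (!object@basis %in% c("single_image", "capped_by_negative",
                           "open_ended", "negative"))
    return("unknown basis")
  if (!is.na(object@titer)) {
    series <- dilutionDenominators(40L)
    if (!any(abs(series - object@titer) < 0.5))
      return("titer must belong to the canonical dilution series")
  }
  TRUE
})

setMethod("show", "IIFImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("IIFImage %d x %d, range [%.3f, %.3f]\n", d[1], d[2],
              min(object@pixels), max(object@pixels)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "SegmentationResult", function(object) {
  d <- dim(object@classMap)
  cat(sprintf("SegmentationResult (%s) %d x %d, %d classes\n",
              object@substrate, d[1], d[2], length(object@classes)))
  tab <- table(factor(object@classes[object@classMap],
                      levels = object@classes))
  cat("  pixels/class:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = " "), "\n")
})

setMethod("show", "AttentionLines", function(object) {
  cat(sprintf("AttentionLines: |roof| = %d px, |floor| = %d px (x%g to raster)\n",
              sum(object@roofLine), sum(object@floorLine),
              object@scaleFactor))
})

setMethod("show", "SideResult", function(object) {
  cat(sprintf("SideResult [%s]: %s  y=%.3f (y+=%.3f, y-=%.3f)  b=%s  n=%d\n",
              object@side, object@call, object@y, object@yPos, object@yNeg,
              ifelse(is.na(object@b), "none", sprintf("%.2f", object@b)),
              object@nInformative))
})

setMethod("show", "EsoClassification", function(object) {
  cat(sprintf("EsoClassification: %s  (BMZ=%.3f, intercellular=%.3f)\n",
              if (object@negative) "negative" else
                paste(object@calls, collapse = "+"),
              object@probs[["BMZ"]], object@probs[["intercellular"]]))
})

setMethod("show", "TiterResult", function(object) {
  cat(sprintf("TiterResult [%s]: %s (%s)\n", object@pattern,
              if (is.na(object@titer)) "negative" else
                sprintf("1:%g", object@titer), object@basis))
})
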