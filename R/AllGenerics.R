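#' Accessors for tissueIIF containers
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a tissueIIF S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "IIFImage", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("imageMetadata", function(object) standardGeneric("imageMetadata"))
#' @rdname accessors
#' @export
setMethod("imageMetadata", "IIFImage", function(object) object@metadata)

#' @rdname accessors
#' @export
setGeneric("classMap", function(object) standardGeneric("classMap"))
#' @rdname accessors
#' @export
setMethod("classMap", "SegmentationResult", function(object) object@classMap)

#' @rdname accessors
#' @export
setGeneric("classProbs", function(object) standardGeneric("classProbs"))
#' @rdname accessors
#' @export
setMethod("classProbs", "SegmentationResult",
          function(object) object@classProbs)

#' @rdname accessors
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setMethod("classLabels", "SegmentationResult",
          function(object) object@classes)

#' @rdname accessors
#' @export
setGeneric("roofLine", function(object) standardGeneric("roofLine"))
#' @rdname accessors
#' @export
setMethod("roofLine", "AttentionLines", function(object) object@roofLine)

#' @rdname accessors
#' @export
setGeneric("floorLine", function(object) standardGeneric("floorLine"))
#' @rdname accessors
#' @export
setMethod("floorLine", "AttentionLines", function(object) object@floorLine)

#' @rdname accessors
#' @export
setGeneric("sideCall", function(object) standardGeneric("sideCall"))
#' @rdname accessors
#' @export
setMethod("sideCall", "SideResult", function(object) object@call)

#' @rdname accessors
#' @export
setGeneric("aggregationScore", function(object) standardGeneric("aggregationScore"))
#' @rdname accessors
#' @export
setMethod("aggregationScore", "SideResult", function(object) object@y)

#' @rdname accessors
#' @export
setGeneric("brightnessScore", function(object) standardGeneric("brightnessScore"))
#' @rdname accessors
#' @export
setMethod("brightnessScore", "SideResult", function(object) object@b)
#' @rdname accessors
#' @export
setMethod("brightnessScore", "RegionIntensity", function(object) object@score)

#' @rdname accessors
#' @export
setGeneric("patternCalls", function(object) standardGeneric("patternCalls"))
#' @rdname accessors
#' @export
setMethod("patternCalls", "EsoClassification", function(object) object@calls)

#' @rdname accessors
#' @export
setGeneric("patternProbs", function(object) standardGeneric("patternProbs"))
#' @rdname accessors
#' @export
setMethod("patternProbs", "EsoClassification", function(object) object@probs)

#' @rdname accessors
#' @export
setGeneric("titerValue", function(object) standardGeneric("titerValue"))
#' @rdname accessors
#' @export
setMethod("titerValue", "TiterResult", function(object) object@titer)

#' @rdname accessors
#' @export
setGeneric("rawIntensity", function(object) standardGeneric("rawIntensity"))
#' @rdname accessors
#' @export
setMethod("rawIntensity", "RegionIntensity",
          function(object) object@rawIntensity)
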