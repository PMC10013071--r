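#' Construct an IIFImage from a numeric matrix
#'
#' @param pixels numeric matrix; values are clipped to \[0, 1\].
#' @param metadata optional named list (`serumId`, `substrate`,
#'   `dilutionIndex`).
#' @return an [IIFImage-class] object.
#' @export
IIFImage <- function(pixels, metadata = list()) {
  pixels <- pmin(pmax(pixels, 0), 1)
  new("IIFImage", pixels = pixels, metadata = metadata)
}

#' Load the green channel of a fluorescence image
#'
#' Reads a TIFF or PNG, keeps the green plane (plane 2 of an RGB image, the
#' only plane of a grayscale image) and normalises intensities to \[0, 1\]
#' by the source dtype maximum. Only the green channel carries the FITC
#' conjugate signal; red counterstain planes are discarded.
#'
#' @param path image file path.
#' @param metadata optional metadata list stored on the result.
#' @return an [IIFImage-class] with pixels in `[row, col]` orientation.
#' @export
loadGreen <- function(path, metadata = list()) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)   # [x, y(, c)] with values already in [0,1]
  nd <- length(dim(dat))
  if (nd == 2L) {
    plane <- dat
  } else if (nd == 3L) {
    nc <- dim(dat)[3]
    plane <- if (nc >= 2L) dat[, , 2L] else dat[, , 1L]
  } else stop("unsupported image layout in ", path)
  # EBImage stores x (column) as the first dimension; transpose to [row, col]
  IIFImage(t(plane), metadata = metadata)
}

#' Write a grayscale image
#'
#' Inverse of [loadGreen()]: writes the raster of an [IIFImage-class] (or a
#' plain matrix in `[row, col]` orientation) as an 8-bit (PNG) or 16-bit
#' (TIFF) single-channel file.
#'
#' @param image [IIFImage-class] or numeric matrix in \[0, 1\].
#' @param path output path; format chosen by extension (.png or .tif/.tiff).
#' @return `path`, invisibly.
#' @export
writeGray <- function(image, path) {
  m <- if (is(image, "IIFImage")) pixels(image) else image
  ext <- tolower(tools::file_ext(path))
  type <- if (ext %in% c("tif", "tiff")) "tiff" else "png"
  bits <- if (type == "tiff") 16L else 8L
  EBImage::writeImage(EBImage::Image(t(m)), path, type = type,
                      bits.per.sample = bits)
  invisible(path)
}

#' Read / write an integer label mask
#'
#' Masks are serialised as single-channel 8-bit PNG where the stored gray
#' level equals `label / 255`; [readMask()] recovers the integer labels.
#' The label tables are documented in [substrateClasses()].
#'
#' @param mask integer matrix of class labels (0-based).
#' @param path PNG path.
#' @return `readMask` returns an integer matrix; `writeMask` returns `path`
#'   invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(max(mask) <= 255L, min(mask) >= 0L)
  EBImage::writeImage(EBImage::Image(t(mask) / 255), path, type = "png",
                      bits.per.sample = 8L)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) dat <- dat[, , 1L]
  m <- t(dat)
  storage.mode(m) <- "double"
  mi <- round(m * 255)
  storage.mode(mi) <- "integer"
  mi
}

#' Resize an image or mask
#'
#' Bilinear resampling for intensity rasters, nearest neighbour for label
#' masks (`mode = "nearest"`), matching the working-size convention of the
#' pipeline (segmentation at 512x512, classification raster at 2048x2048 by
#' default; both configurable). Non-square inputs are resized
#' anisotropically; no aspect-ratio padding is applied and attention
#' geometry is always computed in working coordinates.
#'
#' @param image [IIFImage-class], or a numeric/integer matrix.
#' @param target integer length-2 `(h, w)`.
#' @param mode `"bilinear"` or `"nearest"`.
#' @return same type as the input, resized to `target`.
#' @export
resizeTo <- function(image, target, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(length(target) == 2L, all(target >= 8L))
  isImg <- is(image, "IIFImage")
  m <- if (isImg) pixels(image) else image
  if (all(dim(m) == target)) {
    out <- m
  } else {
    filt <- if (mode == "bilinear") "bilinear" else "none"
    # EBImage's first dimension is our row dimension (consistent transpose-free
    # use is safe because resize treats dims symmetrically)
    out <- EBImage::imageData(EBImage::resize(EBImage::Image(m),
                                              w = target[1], h = target[2],
                                              filter = filt))
    if (mode == "bilinear") out <- pmin(pmax(out, min(m)), max(m))
    if (is.integer(m)) storage.mode(out) <- "integer"
  }
  out <- matrix(out, target[1], target[2])
  if (isImg) IIFImage(out, metadata = imageMetadata(image)) else out
}

#' Binary dilation by a pixel-grid disc
#'
#' Minkowski dilation of a logical mask with the Euclidean disc of diameter
#' `diameterPx` centred on the pixel grid: the structuring element contains
#' every integer offset `(dr, dc)` with `sqrt(dr^2 + dc^2) <= diameterPx/2`.
#' For the default diameter 3 this is the full 3x3 neighbourhood (the
#' diagonal offset has length `sqrt(2) <= 1.5`). Used to expand the
#' segmented roof/floor/interspace regions before intersecting them into
#' attention lines.
#'
#' @param mask logical matrix.
#' @param diameterPx odd positive integer disc diameter in pixels.
#' @return logical matrix of the same shape, a superset of `mask`.
#' @export
dilateDisc <- function(mask, diameterPx = 3L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (diameterPx < 1L || diameterPx %% 2L == 0L)
    stop("diameterPx must be an odd positive integer")
  r <- diameterPx / 2
  k <- floor(r)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  h <- nrow(mask); w <- ncol(mask)
  for (dr in -k:k) for (dc in -k:k) {
    if (dr * dr + dc * dc > r * r + 1e-9) next
    ro <- max(1, 1 + dr):min(h, h + dr)
    co <- max(1, 1 + dc):min(w, w + dc)
    ri <- ro - dr
    ci <- co - dc
    out[ro, co] <- out[ro, co] | mask[ri, ci]
  }
  out
}

#' Class tables of the two substrates
#'
#' Integer label tables used in masks and segmentation outputs. Label 0 is
#' always background; the remaining labels follow the anatomy of the
#' substrate (salt-split skin: epidermal roof, dermal floor and the
#' interspace opened by the 1M NaCl split; esophagus: the tissue layers from
#' the epithelium down to the longitudinal muscle, with the basement
#' membrane zone (BMZ) as its own thin class).
#'
#' @param substrate `"split_skin"` or `"esophagus"`.
#' @return named integer vector mapping class name to mask label.
#' @export
substrateClasses <- function(substrate = c("split_skin", "esophagus")) {
  substrate <- match.arg(substrate)
  if (substrate == "split_skin") {
    c(background = 0L, roof = 1L, floor = 2L, interspace = 3L)
  } else {
    c(background = 0L, epithelium = 1L, BMZ = 2L, lamina_propria = 3L,
      muscular_mucosa = 4L, circular_muscle = 5L, longitudinal_muscle = 6L)
  }
}

#' Valid patterns per substrate
#' @param substrate `"split_skin"` or `"esophagus"`.
#' @return character vector of individual pattern names (excluding
#'   `"none"`/`"both"` composites).
#' @export
substratePatterns <- function(substrate = c("split_skin", "esophagus")) {
  substrate <- match.arg(substrate)
  if (substrate == "split_skin") c("epidermal", "dermal")
  else c("BMZ", "intercellular")
}
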