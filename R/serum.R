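#' Serum-level result over a dilution series
#'
#' Classifies every image of a serum's dilution series and compiles a
#' patient-based result: per-pattern calls and brightness scores per
#' dilution, and the estimated endpoint titer per pattern via
#' [titerSeries()].
#'
#' @param images list of [IIFImage-class] (or scene lists with `$image`),
#'   ordered by increasing dilution.
#' @param dilutionIndices integer vector of dilution indices `k` (1 = 1:10);
#'   defaults to `seq_along(images)`.
#' @param substrate `"split_skin"` or `"esophagus"`.
#' @param models list of fitted models: for split skin `seg`, `roof`,
#'   `floor`; for esophagus `seg`, `cls`.
#' @param clsSize,nPatches,threshold,seed forwarded to the per-image
#'   predictors (split skin).
#' @param thresholds,bandPx,q forwarded to [predictEso()] (esophagus).
#' @return list with `perImage` (data.frame: one row per image and pattern
#'   with call and score) and `titer` (named list of
#'   [TiterResult-class] per pattern).
#' @export
predictSerum <- function(images, dilutionIndices = NULL,
                         substrate = c("split_skin", "esophagus"), models,
                         clsSize = 2048L, nPatches = 40L, threshold = 0.5,
                         seed = 1L,
                         thresholds = c(BMZ = 0.5, intercellular = 0.5),
                         bandPx = 10L, q = 0.95) {
  substrate <- match.arg(substrate)
  if (is.null(dilutionIndices)) dilutionIndices <- seq_along(images)
  stopifnot(length(images) == length(dilutionIndices))
  pats <- substratePatterns(substrate)
  rows <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (is.list(img) && !is(img, "IIFImage")) img <- img$image
    if (substrate == "split_skin") {
      pr <- predictSSS(img, models$seg, models$roof, models$floor,
                       clsSize = clsSize, nPatches = nPatches,
                       threshold = threshold, seed = seed + i)
      sides <- list(epidermal = pr$roof, dermal = pr$floor)
      for (pat in pats) {
        sr <- sides[[pat]]
        rows[[length(rows) + 1L]] <- data.frame(
          k = dilutionIndices[i], pattern = pat,
          call = sideCall(sr) == "positive",
          s = if (is.na(brightnessScore(sr))) NA_real_ else
            min(5, max(1, brightnessScore(sr))),
          stringsAsFactors = FALSE)
      }
    } else {
      pr <- predictEso(img, models$seg, models$cls, thresholds = thresholds,
                       bandPx = bandPx, q = q)
      for (pat in pats) {
        called <- pat %in% patternCalls(pr$classification)
        sc <- if (called && !is.null(pr$intensity[[pat]]))
          brightnessScore(pr$intensity[[pat]]) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          k = dilutionIndices[i], pattern = pat, call = called, s = sc,
          stringsAsFactors = FALSE)
      }
    }
  }
  perImage <- do.call(rbind, rows)
  titers <- lapply(pats, function(pat) {
    e <- perImage[perImage$pattern == pat, c("k", "call", "s")]
    e <- e[order(e$k), ]
    e$s[e$call & is.na(e$s)] <- 1    # positive call without score: weakest
    titerSeries(e, pattern = pat)
  })
  names(titers) <- pats
  list(perImage = perImage, titer = titers)
}
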