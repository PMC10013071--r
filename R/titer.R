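#' Canonical half-log dilution series
#'
#' Dilution denominators 10, 32, 100, 320, 1000, 3200, 10000, ... continued
#' by the alternating x3.2 / x3.125 half-log-step pattern. Index 1 is 1:10.
#'
#' @param n number of terms.
#' @return numeric vector of length `n`.
#' @export
dilutionDenominators <- function(n = 10L) {
  stopifnot(n >= 1L)
  d <- numeric(n)
  d[1] <- 10
  if (n > 1L) for (i in 2L:n) {
    d[i] <- if (i %% 2L == 0L) d[i - 1L] * 3.2 else d[i - 1L] * 3.125
  }
  round(d)
}

#' Titer from a single dilution image
#'
#' A pattern detected on the image of dilution index `k` with brightness
#' score `s` (score units, \[1, 5\]) is converted to a titer by index
#' addition on the canonical series: the titer denominator is
#' `d[k + round(s) - 1]`. A brighter pattern at a given dilution implies a
#' higher endpoint titer. `s` is rounded half-up to the nearest integer
#' before indexing.
#'
#' @param k dilution index (1-based; 1 is 1:10).
#' @param s brightness score in \[1, 5\].
#' @param pattern pattern name recorded on the result.
#' @return a [TiterResult-class].
#' @export
titerSingle <- function(k, s, pattern = "pattern") {
  stopifnot(k >= 1L)
  if (is.na(s) || s < 1 - 1e-9 || s > 5 + 1e-9)
    stop("brightness score must lie in [1, 5]")
  idx <- k + floor(s + 0.5) - 1L
  d <- dilutionDenominators(idx + 1L)
  new("TiterResult", pattern = pattern, titer = d[idx], basis = "single_image")
}

#' Titer from a dilution series
#'
#' Combines per-image calls and brightness scores over a dilution series.
#' If some image is negative for the pattern, the lowest such dilution
#' defines the total dilution: the titer is computed with [titerSingle()]
#' from the highest-dilution positive image below it and capped one step
#' below the first negative dilution. If no image is negative, the
#' highest-dilution image is used open-ended. An all-negative series yields
#' a negative result with no titer.
#'
#' @param entries data.frame with columns `k` (dilution index, strictly
#'   increasing), `call` (logical or "positive"/"negative") and `s`
#'   (brightness score, may be `NA` on negative images).
#' @param pattern pattern name recorded on the result.
#' @return a [TiterResult-class].
#' @export
titerSeries <- function(entries, pattern = "pattern") {
  stopifnot(is.data.frame(entries), nrow(entries) >= 1L,
            all(c("k", "call", "s") %in% names(entries)))
  if (is.character(entries$call)) entries$call <- entries$call == "positive"
  if (any(diff(entries$k) <= 0)) stop("dilution indices must be increasing")
  neg <- entries$k[!entries$call]
  pos <- entries[entries$call, , drop = FALSE]
  if (nrow(pos) == 0L)
    return(new("TiterResult", pattern = pattern, titer = NA_real_,
               basis = "negative"))
  if (length(neg) == 0L) {
    use <- pos[which.max(pos$k), ]
    tr <- titerSingle(use$k, use$s, pattern)
    return(new("TiterResult", pattern = pattern, titer = tr@titer,
               basis = if (nrow(entries) == 1L) "single_image" else
                 "open_ended"))
  }
  m <- min(neg)
  below <- pos[pos$k < m, , drop = FALSE]
  if (nrow(below) == 0L)
    return(new("TiterResult", pattern = pattern, titer = NA_real_,
               basis = "negative"))
  use <- below[which.max(below$k), ]
  tr <- titerSingle(use$k, use$s, pattern)
  d <- dilutionDenominators(max(m, use$k + 4L))
  capped <- min(tr@titer, d[m - 1L])
  new("TiterResult", pattern = pattern, titer = capped,
      basis = "capped_by_negative")
}

#' Agreement statistics from a confusion matrix
#'
#' Accuracy, positive percent agreement (PPA) and negative percent
#' agreement (NPA) in percent, with expert visual reading as the reference:
#' `accuracy = 100 (tp + tn) / n`, `PPA = 100 tp / (tp + fn)`,
#' `NPA = 100 tn / (tn + fp)`.
#'
#' @param tp,fp,fn,tn non-negative integer cell counts (prediction vs
#'   reference reading).
#' @return named numeric vector `accuracy`, `PPA`, `NPA` (percent).
#' @export
confusionMetrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  n <- tp + fp + fn + tn
  if (n == 0 || tp + fn == 0 || tn + fp == 0)
    stop("confusion matrix has an empty margin; metrics undefined")
  c(accuracy = 100 * (tp + tn) / n,
    PPA = 100 * tp / (tp + fn),
    NPA = 100 * tn / (tn + fp))
}

#' Titer deviation histogram
#'
#' Deviation of predicted from reference titers in whole dilution steps
#' (index difference on the canonical series); negative values indicate
#' underestimation. Only pairs where both readings are positive with the
#' same pattern are informative; pairs with a missing side are skipped with
#' a message.
#'
#' @param predTiters,refTiters numeric vectors of titer denominators, `NA`
#'   for negative; paired by position (same serum and pattern).
#' @return named integer table of step deviations.
#' @export
titerDeviation <- function(predTiters, refTiters) {
  stopifnot(length(predTiters) == length(refTiters))
  d <- dilutionDenominators(40L)
  toIdx <- function(x) {
    i <- vapply(x, function(v) {
      if (is.na(v)) return(NA_integer_)
      j <- which(abs(d - v) < 0.5)
      if (!length(j)) stop("titer ", v, " not on the canonical series")
      j[1]
    }, integer(1))
    i
  }
  pi <- toIdx(predTiters); ri <- toIdx(refTiters)
  keep <- !is.na(pi) & !is.na(ri)
  if (any(!keep))
    message(sum(!keep), " unmatched pair(s) skipped in titer deviation")
  dev <- pi[keep] - ri[keep]
  table(deviation = dev)
}

#' Validation-study confusion matrices
#'
#' The published clinical validation counts of the automated reader against
#' conventional visual evaluation: per-substrate combined columns and the
#' per-pattern columns (salt-split skin: epidermal, dermal; esophagus: BMZ,
#' intercellular). These serve as fixed reference inputs for
#' [confusionMetrics()]. Counts are cell values; the intercellular column of
#' the esophagus table is stored with its internally consistent cell sums.
#'
#' @return data.frame with columns `table`, `column`, `tp`, `fp`, `fn`, `tn`.
#' @export
validationTables <- function() {
  data.frame(
    table = c(rep("split_skin", 3), rep("esophagus", 3)),
    column = c("combined", "epidermal", "dermal",
               "combined", "BMZ", "intercellular"),
    tp = c(31L, 25L, 8L, 46L, 27L, 20L),
    fp = c(4L, 3L, 3L, 0L, 2L, 0L),
    fn = c(1L, 1L, 0L, 3L, 3L, 0L),
    tn = c(73L, 80L, 98L, 61L, 78L, 90L),
    stringsAsFactors = FALSE
  )
}
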