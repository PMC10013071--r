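# Independent oracles used across test files.

# brute-force Minkowski dilation: enumerate the disc offsets for every true
# pixel and mark the translated positions (pixel-by-pixel, no vectorised
# shifts shared with the implementation)
bruteDilate <- function(mask, diameterPx = 3L) {
  r <- diameterPx / 2
  k <- floor(r)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts)) for (i in seq_len(nrow(pts))) {
    for (dr in -k:k) for (dc in -k:k) {
      if (dr * dr + dc * dc > r * r + 1e-9) next
      rr <- pts[i, 1] + dr; cc <- pts[i, 2] + dc
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) out[rr, cc] <- TRUE
    }
  }
  out
}

# fast independent dilation oracle (padded box convolution), used for the
# large randomised equivalence runs
convDilate <- function(mask, diameterPx = 3L) {
  k <- floor(diameterPx / 2)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2 * k, w + 2 * k)
  pad[(k + 1):(k + h), (k + 1):(k + w)] <- mask * 1
  r <- diameterPx / 2
  ker <- outer((-k:k)^2, (-k:k)^2, "+") <= r * r + 1e-9
  out <- EBImage::imageData(EBImage::filter2(EBImage::Image(pad), ker * 1))
  out[(k + 1):(k + h), (k + 1):(k + w)] > 0.5
}

# literal evaluation of the attention-line set equations on a label mask
# (0 = background, 1 = roof, 2 = floor, 3 = interspace)
oracleAttentionLines <- function(labels, dil = convDilate) {
  dR <- dil(labels == 1L)
  dF <- dil(labels == 2L)
  dI <- dil(labels == 3L)
  list(roof = dR & (dF | dI), floor = dF & (dR | dI))
}

# type-7 quantile by explicit order statistics
oracleQuantile7 <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
}

# tiny scene cache shared across test files
.sceneCache <- new.env(parent = emptyenv())
cachedScene <- function(key, expr) {
  got <- .sceneCache[[key]]
  if (is.null(got)) {
    got <- force(expr)
    .sceneCache[[key]] <- got
  }
  got
}

# synthetic patch-result data frames for aggregation tests: argmax-label
# probability p for each listed patch, remainder spread over other labels
mkResults <- function(pos = numeric(0), neg = numeric(0),
                      bg = numeric(0), unc = numeric(0),
                      bright = NULL) {
  rows <- list()
  add <- function(p, lab) {
    r <- c(p_positive = 0.0, p_negative = 0.0, p_background = 0.0,
           p_unclear = 0.0)
    r[paste0("p_", lab)] <- p
    r[setdiff(names(r), paste0("p_", lab))] <- (1 - p) / 3
    as.list(r)
  }
  for (p in pos) rows[[length(rows) + 1]] <- c(add(p, "positive"),
                                               label = "positive")
  for (p in neg) rows[[length(rows) + 1]] <- c(add(p, "negative"),
                                               label = "negative")
  for (p in bg) rows[[length(rows) + 1]] <- c(add(p, "background"),
                                              label = "background")
  for (p in unc) rows[[length(rows) + 1]] <- c(add(p, "unclear"),
                                               label = "unclear")
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df$brightness <- if (is.null(bright)) 3 else bright
  df$isPadding <- FALSE
  df
}
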