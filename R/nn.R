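# Minimal convolutional-network engine used by the segmentation, patch and
# esophagus classifiers. Feature maps are stored as (H*W) x C matrices in
# column-major pixel order; 3x3 convolutions are evaluated as nine shifted
# matrix products, which keeps everything inside BLAS. Only what the
# pipeline needs is implemented: 3x3 conv, ReLU, 2x average pooling, 2x
# nearest upsampling with summation skips, global average pooling, dense
# layers, softmax/sigmoid heads and ADAM.

.convOffsets <- expand.grid(dr = -1:1, dc = -1:1)

.idxCache <- new.env(parent = emptyenv())

# index vectors (out, in) per 3x3 offset for an H x W raster, memoised
convIdx <- function(H, W) {
  key <- paste0(H, "x", W)
  got <- .idxCache[[key]]
  if (!is.null(got)) return(got)
  out <- vector("list", 9L)
  for (k in seq_len(9L)) {
    dr <- .convOffsets$dr[k]; dc <- .convOffsets$dc[k]
    rs <- max(1, 1 - dr):min(H, H - dr)
    cs <- max(1, 1 - dc):min(W, W - dc)
    io <- as.vector(outer(rs, (cs - 1L) * H, "+"))
    ii <- as.vector(outer(rs + dr, (cs + dc - 1L) * H, "+"))
    out[[k]] <- list(io = io, ii = ii)
  }
  .idxCache[[key]] <- out
  out
}

# zero-padded index scheme: one scatter of the raster into a (H+2) x (W+2)
# frame per sample, then each 3x3 offset becomes a pure gather and a full
# matrix add — no submatrix assignments in the hot path
padIdx <- function(H, W, B) {
  key <- paste0("pad", H, "x", W, "x", B)
  got <- .idxCache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + 2L
  frame <- (B > 0L)
  off <- (seq_len(B) - 1L) * Hp * (W + 2L)
  rs <- seq_len(H); cs <- seq_len(W)
  base <- as.vector(outer(rs + 1L, cs * Hp, "+"))
  pad <- as.vector(outer(base, off, "+"))
  g <- vector("list", 9L)
  for (k in seq_len(9L)) {
    dr <- .convOffsets$dr[k]; dc <- .convOffsets$dc[k]
    bk <- as.vector(outer(rs + 1L + dr, (cs + dc) * Hp, "+"))
    g[[k]] <- as.vector(outer(bk, off, "+"))
  }
  got <- list(pad = pad, g = g, nPad = B * Hp * (W + 2L))
  .idxCache[[key]] <- got
  got
}

poolIdx <- function(H, W) {
  key <- paste0("p", H, "x", W)
  got <- .idxCache[[key]]
  if (!is.null(got)) return(got)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  ro <- seq_len(Ho); co <- seq_len(Wo)
  out <- vector("list", 4L)
  k <- 1L
  for (b in 0:1) for (a in 0:1) {
    out[[k]] <- as.vector(outer(2L * ro - 1L + a, (2L * co - 2L + b) * H, "+"))
    k <- k + 1L
  }
  .idxCache[[key]] <- out
  out
}

convParam <- function(cin, cout, zero = FALSE) {
  sd <- sqrt(2 / (9 * cin))
  W <- lapply(seq_len(9L), function(k) {
    if (zero) matrix(0, cin, cout)
    else matrix(stats::rnorm(cin * cout, sd = sd), cin, cout)
  })
  list(W = W, b = numeric(cout))
}

denseParam <- function(cin, cout, zero = FALSE) {
  sd <- sqrt(2 / cin)
  list(W = if (zero) matrix(0, cin, cout)
           else matrix(stats::rnorm(cin * cout, sd = sd), cin, cout),
       b = numeric(cout))
}

convFwdP <- function(x, p, H, W, B) {
  ix <- padIdx(H, W, B)
  xp <- matrix(0, ix$nPad, ncol(x))
  xp[ix$pad, ] <- x
  out <- matrix(p$b, nrow(x), length(p$b), byrow = TRUE)
  for (k in seq_len(9L)) {
    out <- out + xp[ix$g[[k]], , drop = FALSE] %*% p$W[[k]]
  }
  out
}

convBwdP <- function(x, dout, p, H, W, B) {
  ix <- padIdx(H, W, B)
  xp <- matrix(0, ix$nPad, ncol(x))
  xp[ix$pad, ] <- x
  dp <- matrix(0, ix$nPad, ncol(dout))
  dp[ix$pad, ] <- dout
  dW <- vector("list", 9L)
  dx <- matrix(0, nrow(x), ncol(x))
  for (k in seq_len(9L)) {
    dW[[k]] <- crossprod(xp[ix$g[[k]], , drop = FALSE], dout)
    # dx(r,c) accumulates dout(r-dr, c-dc) W_k: gather with the opposite
    # offset (the offset table is centrally symmetric: k <-> 10-k)
    dx <- dx + dp[ix$g[[10L - k]], , drop = FALSE] %*% t(p$W[[k]])
  }
  list(dx = dx, grad = list(W = dW, b = colSums(dout)))
}

convFwd <- function(x, p, H, W) convFwdP(x, p, H, W, 1L)
convBwd <- function(x, dout, p, H, W) convBwdP(x, dout, p, H, W, 1L)

reluFwd <- function(x) x * (x > 0)
reluBwd <- function(x, dout) dout * (x > 0)

poolFwd <- function(x, H, W) {
  i <- poolIdx(H, W)
  (x[i[[1]], , drop = FALSE] + x[i[[2]], , drop = FALSE] +
   x[i[[3]], , drop = FALSE] + x[i[[4]], , drop = FALSE]) / 4
}

poolBwd <- function(dout, H, W) {
  i <- poolIdx(H, W)
  dx <- matrix(0, H * W, ncol(dout))
  for (k in 1:4) dx[i[[k]], ] <- dout / 4
  dx
}

upFwd <- function(x, H, W) {           # H, W: the *output* (fine) size
  i <- poolIdx(H, W)
  out <- matrix(0, H * W, ncol(x))
  for (k in 1:4) out[i[[k]], ] <- x
  out
}

upBwd <- function(dout, H, W) {        # H, W: the fine size of dout
  i <- poolIdx(H, W)
  dout[i[[1]], , drop = FALSE] + dout[i[[2]], , drop = FALSE] +
    dout[i[[3]], , drop = FALSE] + dout[i[[4]], , drop = FALSE]
}

softmaxRows <- function(z) {
  m <- z[, 1L]
  for (k in seq_len(ncol(z))[-1L]) m <- pmax(m, z[, k])
  e <- exp(z - as.numeric(m))
  e / rowSums(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- ADAM over nested parameter lists --------------------------------------

mapStruct <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    byName <- !is.null(names(a)) && !is.null(names(b)) &&
      all(names(a) %in% names(b))
    for (i in seq_along(a)) {
      bi <- if (byName) b[[names(a)[i]]] else b[[i]]
      out[[i]] <- mapStruct(f, a[[i]], bi)
    }
    out
  } else f(a, b)
}

zerosLike <- function(p) {
  if (is.list(p)) lapply(p, zerosLike) else p * 0
}

adamInit <- function(params) {
  list(m = zerosLike(params), v = zerosLike(params), t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-3,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- mapStruct(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- mapStruct(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- mapStruct(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  params <- mapStruct(`-`, params, upd)
  list(params = params, state = state)
}

addStruct <- function(a, b) mapStruct(`+`, a, b)

# ---- encoder-decoder segmenter ---------------------------------------------

# Residual-free scaled-down encoder-decoder: two conv blocks per level,
# three resolution levels, summation skip connections, 1x1 conv head.
unetInit <- function(cin, nClasses, channels = 8L) {
  C <- channels
  list(e1a = convParam(cin, C), e1b = convParam(C, C),
       e2a = convParam(C, C),   e2b = convParam(C, C),
       e3a = convParam(C, C),   e3b = convParam(C, C),
       d2  = convParam(C, C),   d1  = convParam(C, C),
       head = denseParam(C, nClasses, zero = TRUE))
}

unetForward <- function(p, x, H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L; H4 <- H %/% 4L; W4 <- W %/% 4L
  z1a <- convFwd(x, p$e1a, H, W);    a1a <- reluFwd(z1a)
  z1b <- convFwd(a1a, p$e1b, H, W);  a1b <- reluFwd(z1b)
  d1  <- poolFwd(a1b, H, W)
  z2a <- convFwd(d1, p$e2a, H2, W2); a2a <- reluFwd(z2a)
  z2b <- convFwd(a2a, p$e2b, H2, W2); a2b <- reluFwd(z2b)
  d2  <- poolFwd(a2b, H2, W2)
  z3a <- convFwd(d2, p$e3a, H4, W4); a3a <- reluFwd(z3a)
  z3b <- convFwd(a3a, p$e3b, H4, W4); a3b <- reluFwd(z3b)
  u2  <- upFwd(a3b, H2, W2) + a2b
  z4  <- convFwd(u2, p$d2, H2, W2);  a4 <- reluFwd(z4)
  u1  <- upFwd(a4, H, W) + a1b
  z5  <- convFwd(u1, p$d1, H, W);    a5 <- reluFwd(z5)
  logits <- sweep(a5 %*% p$head$W, 2, p$head$b, "+")
  list(x = x, z1a = z1a, a1a = a1a, z1b = z1b, a1b = a1b, d1 = d1,
       z2a = z2a, a2a = a2a, z2b = z2b, a2b = a2b, d2 = d2,
       z3a = z3a, a3a = a3a, z3b = z3b, a3b = a3b, u2 = u2, z4 = z4,
       a4 = a4, u1 = u1, z5 = z5, a5 = a5, logits = logits,
       H = H, W = W)
}

unetBackward <- function(p, cache, dlogits) {
  H <- cache$H; W <- cache$W
  H2 <- H %/% 2L; W2 <- W %/% 2L
  gHead <- list(W = crossprod(cache$a5, dlogits), b = colSums(dlogits))
  da5 <- dlogits %*% t(p$head$W)
  dz5 <- reluBwd(cache$z5, da5)
  b5 <- convBwd(cache$u1, dz5, p$d1, H, W)
  du1 <- b5$dx
  da1b_skip <- du1
  da4 <- upBwd(du1, H, W)
  dz4 <- reluBwd(cache$z4, da4)
  b4 <- convBwd(cache$u2, dz4, p$d2, H2, W2)
  du2 <- b4$dx
  da2b_skip <- du2
  da3b <- upBwd(du2, H2, W2)
  dz3b <- reluBwd(cache$z3b, da3b)
  H4 <- H %/% 4L; W4 <- W %/% 4L
  b3b <- convBwd(cache$a3a, dz3b, p$e3b, H4, W4)
  dz3a <- reluBwd(cache$z3a, b3b$dx)
  b3a <- convBwd(cache$d2, dz3a, p$e3a, H4, W4)
  dd2 <- b3a$dx
  da2b <- poolBwd(dd2, H2, W2) + da2b_skip
  dz2b <- reluBwd(cache$z2b, da2b)
  b2b <- convBwd(cache$a2a, dz2b, p$e2b, H2, W2)
  dz2a <- reluBwd(cache$z2a, b2b$dx)
  b2a <- convBwd(cache$d1, dz2a, p$e2a, H2, W2)
  dd1 <- b2a$dx
  da1b <- poolBwd(dd1, H, W) + da1b_skip
  dz1b <- reluBwd(cache$z1b, da1b)
  b1b <- convBwd(cache$a1a, dz1b, p$e1b, H, W)
  dz1a <- reluBwd(cache$z1a, b1b$dx)
  b1a <- convBwd(cache$x, dz1a, p$e1a, H, W)
  list(e1a = b1a$grad, e1b = b1b$grad, e2a = b2a$grad, e2b = b2b$grad,
       e3a = b3a$grad, e3b = b3b$grad, d2 = b4$grad, d1 = b5$grad,
       head = gHead)
}

# ---- batched spatial ops ---------------------------------------------------
# A batch of B square S x S maps is stacked sample-major into a (B*S*S) x C
# matrix; shift/pool index vectors are replicated per sample with an offset
# of S*S so convolutions never bleed across patch boundaries.

batchPoolIdx <- function(S, B) {
  key <- paste0("bp", S, "x", B)
  got <- .idxCache[[key]]
  if (!is.null(got)) return(got)
  base <- poolIdx(S, S)
  off <- (seq_len(B) - 1L) * S * S
  out <- lapply(base, function(ix) as.vector(outer(ix, off, "+")))
  .idxCache[[key]] <- out
  out
}

convFwdB <- function(x, p, S, B) convFwdP(x, p, S, S, B)
convBwdB <- function(x, dout, p, S, B) convBwdP(x, dout, p, S, S, B)

poolFwdB <- function(x, S, B) {
  i <- batchPoolIdx(S, B)
  (x[i[[1]], , drop = FALSE] + x[i[[2]], , drop = FALSE] +
   x[i[[3]], , drop = FALSE] + x[i[[4]], , drop = FALSE]) / 4
}

poolBwdB <- function(dout, S, B) {
  i <- batchPoolIdx(S, B)
  dx <- matrix(0, B * S * S, ncol(dout))
  for (k in 1:4) dx[i[[k]], ] <- dout / 4
  dx
}

# batched trunk: returns pooled descriptors as a B x 3C matrix
# (per-sample channel mean, channel max, centre/attention-weighted mean)
trunkForwardB <- function(p, x, S, B, nStages, poolWeights) {
  cache <- list(sizes = integer(0), z = list(), inp = list())
  cur <- x; s <- S
  for (st in seq_len(nStages)) {
    cache$inp[[st]] <- cur
    cache$sizes[st] <- s
    z <- convFwdB(cur, p[[paste0("c", st)]], s, B)
    a <- reluFwd(z)
    cache$z[[st]] <- z
    cur <- poolFwdB(a, s, B)
    s <- s %/% 2L
  }
  n <- s * s
  C <- ncol(cur)
  grp <- rep(seq_len(B), each = n)
  gMean <- rowsum(cur, grp) / n
  gMax <- matrix(0, B, C)
  amax <- matrix(0L, B, C)
  for (c_ in seq_len(C)) {
    m <- matrix(cur[, c_], n, B)
    am <- max.col(t(m), ties.method = "first")
    amax[, c_] <- am
    gMax[, c_] <- m[cbind(am, seq_len(B))]
  }
  wn <- poolWeights / sum(poolWeights)
  gW <- matrix(0, B, C)
  for (c_ in seq_len(C)) gW[, c_] <- colSums(matrix(cur[, c_], n, B) * wn)
  cache$out <- cur; cache$n <- n; cache$amax <- amax; cache$wn <- wn
  cache$g <- cbind(gMean, gMax, gW)
  cache
}

trunkBackwardB <- function(p, cache, dg, B, nStages) {
  n <- cache$n
  C <- ncol(cache$out)
  dMean <- dg[, seq_len(C), drop = FALSE]
  dMax <- dg[, C + seq_len(C), drop = FALSE]
  dWst <- dg[, 2L * C + seq_len(C), drop = FALSE]
  rows <- rep(seq_len(B), each = n)
  dcur <- dMean[rows, , drop = FALSE] / n +
    rep(cache$wn, B) * dWst[rows, , drop = FALSE]
  for (c_ in seq_len(C)) {
    at <- (seq_len(B) - 1L) * n + cache$amax[, c_]
    dcur[at, c_] <- dcur[at, c_] + dMax[, c_]
  }
  grads <- list()
  for (st in rev(seq_len(nStages))) {
    s <- cache$sizes[st]
    da <- poolBwdB(dcur, s, B)
    dz <- reluBwd(cache$z[[st]], da)
    b <- convBwdB(cache$inp[[st]], dz, p[[paste0("c", st)]], s, B)
    grads[[paste0("c", st)]] <- b$grad
    dcur <- b$dx
  }
  grads
}

# ---- small conv classifier trunk (patch net / esophagus net) ---------------

# conv+ReLU+pool stages down to a coarse map, then global pooling. The
# pooled descriptor concatenates the mean and the max response per channel:
# thin bright structures (a fluorescent band a few pixels wide) barely move
# a plain average but dominate the max, so both statistics are kept. An
# optional weight map adds a third, attention-weighted mean (used by the
# dual-input esophagus classifier, where the BMZ mask focuses pooling).
trunkInit <- function(cin, channels, nStages) {
  p <- list()
  for (s in seq_len(nStages)) {
    p[[paste0("c", s)]] <- convParam(if (s == 1L) cin else channels, channels)
  }
  p
}

trunkForward <- function(p, x, H, W, nStages, poolWeights = NULL) {
  cache <- list(sizes = list(), z = list(), a = list(), inp = list())
  cur <- x; h <- H; w <- W
  for (s in seq_len(nStages)) {
    cache$inp[[s]] <- cur
    cache$sizes[[s]] <- c(h, w)
    z <- convFwd(cur, p[[paste0("c", s)]], h, w)
    a <- reluFwd(z)
    cache$z[[s]] <- z; cache$a[[s]] <- a
    cur <- poolFwd(a, h, w)
    h <- h %/% 2L; w <- w %/% 2L
  }
  cache$out <- cur            # (h*w) x C
  cache$outSize <- c(h, w)
  amax <- max.col(t(cur), ties.method = "first")   # argmax pixel per channel
  cache$amax <- amax
  gMean <- colMeans(cur)
  gMax <- cur[cbind(amax, seq_along(amax))]
  if (!is.null(poolWeights)) {
    if (!is.list(poolWeights)) poolWeights <- list(poolWeights)
    wns <- lapply(poolWeights, function(w) {
      s <- sum(w)
      if (s > 0) w / s else rep(1 / length(w), length(w))
    })
    cache$poolW <- wns
    g <- c(gMean, gMax,
           unlist(lapply(wns, function(wn) as.vector(crossprod(cur, wn)))))
  } else {
    g <- c(gMean, gMax)
  }
  cache$g <- g
  cache
}

trunkBackward <- function(p, cache, dg, nStages) {
  n <- prod(cache$outSize)
  C <- ncol(cache$out)
  dMean <- dg[seq_len(C)]
  dMax <- dg[C + seq_len(C)]
  dcur <- matrix(dMean, n, C, byrow = TRUE) / n
  dcur[cbind(cache$amax, seq_len(C))] <-
    dcur[cbind(cache$amax, seq_len(C))] + dMax
  if (!is.null(cache$poolW)) {
    for (j in seq_along(cache$poolW)) {
      dW <- dg[(1L + j) * C + seq_len(C)]
      dcur <- dcur + outer(cache$poolW[[j]], dW)
    }
  }
  grads <- list()
  for (s in rev(seq_len(nStages))) {
    hw <- cache$sizes[[s]]
    da <- poolBwd(dcur, hw[1], hw[2])
    dz <- reluBwd(cache$z[[s]], da)
    b <- convBwd(cache$inp[[s]], dz, p[[paste0("c", s)]], hw[1], hw[2])
    grads[[paste0("c", s)]] <- b$grad
    dcur <- b$dx
  }
  grads
}

denseFwd <- function(g, p) as.vector(g %*% p$W) + p$b

# gradient of a dense layer applied to vector g with upstream dout
denseBwd <- function(g, p, dout) {
  list(grad = list(W = outer(g, dout), b = dout),
       dg = as.vector(p$W %*% dout))
}

# ---- losses ----------------------------------------------------------------

#' Generalized Dice loss
#'
#' Multi-class Dice overlap loss with inverse-squared-volume class weights,
#' `GDL = 1 - 2 (sum_l w_l sum_n r_ln p_ln) / (sum_l w_l sum_n (r_ln + p_ln))`
#' with `w_l = 1 / max(sum_n r_ln, 1)^2`. The weighting equalises the
#' contribution of large and small classes, which makes the loss robust to
#' the extreme region-size imbalance of tissue segmentation (a thin
#' interspace or BMZ versus large muscle areas). Classes absent from the
#' reference get their weight clamped via the `max(., 1)` guard.
#'
#' @param predProbs numeric matrix or array of predicted per-pixel class
#'   probabilities (`n x k`, or `h x w x k`).
#' @param truthOnehot one-hot reference of the same shape.
#' @return scalar loss in \[0, 1\]; 0 exactly on a perfect prediction.
#' @export
generalizedDiceLoss <- function(predProbs, truthOnehot) {
  p <- asProbMatrix(predProbs)
  r <- asProbMatrix(truthOnehot)
  stopifnot(identical(dim(p), dim(r)))
  gdlParts(p, r)$loss
}

asProbMatrix <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) matrix(x, d[1] * d[2], d[3]) else as.matrix(x)
}

gdlParts <- function(p, r) {
  w <- 1 / pmax(colSums(r), 1)^2
  num <- sum(w * colSums(r * p))
  den <- sum(w * (colSums(r) + colSums(p)))
  list(loss = 1 - 2 * num / den, w = w, num = num, den = den)
}

# loss and gradient wrt probabilities
gdlWithGrad <- function(p, r) {
  parts <- gdlParts(p, r)
  w <- parts$w; num <- parts$num; den <- parts$den
  dp <- -2 * (sweep(r, 2, w, "*") * den -
                matrix(w, nrow(p), ncol(p), byrow = TRUE) * num) / den^2
  list(loss = parts$loss, dp = dp)
}

# chain a gradient wrt softmax outputs back to logits, row-wise
softmaxChain <- function(probs, dp) {
  s <- rowSums(probs * dp)
  probs * (dp - s)
}

# optional per-class weights rebalance rare classes (inverse frequency,
# capped); weights default to 1 for plain cross-entropy
crossEntropyWithGrad <- function(probs, onehot, classWeights = NULL) {
  eps <- 1e-12
  n <- nrow(probs)
  if (is.null(classWeights)) {
    loss <- -sum(onehot * log(probs + eps)) / n
    dlogits <- (probs - onehot) / n
  } else {
    wpix <- as.vector(onehot %*% classWeights)
    loss <- -sum(wpix * rowSums(onehot * log(probs + eps))) / n
    dlogits <- wpix * (probs - onehot) / n
  }
  list(loss = loss, dlogits = dlogits)
}

# inverse-frequency class weights, capped, for a one-hot target
invFreqWeights <- function(onehot, cap = 10) {
  n <- nrow(onehot); K <- ncol(onehot)
  freq <- colSums(onehot)
  pmin(n / (K * pmax(freq, 1)), cap)
}
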