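## Minimal neural-network kernels with explicit forward/backward passes.
## Everything is plain double-precision matrix algebra; layouts:
##   dense activations  : N x d matrices (rows = tokens or samples)
##   image batches      : [B, H, W, C] arrays
##   token volumes      : [T, H, W, p] arrays (slices x patch grid x channels)
## These kernels exist because the adapter/Slider forward-backward is the
## package's own contribution and is trained here on CPU-scale problems.

#' @keywords internal
#' @noRd
nnActivation <- function(name) {
  switch(name,
    gelu = list(
      f = function(x) x * stats::pnorm(x),
      df = function(x) stats::pnorm(x) + x * stats::dnorm(x)),
    relu = list(
      f = function(x) pmax(x, 0),
      df = function(x) (x > 0) * 1),
    identity = list(f = function(x) x, df = function(x) x * 0 + 1),
    stop("unknown activation: ", name))
}

#' @keywords internal
#' @noRd
nnLinearFwd <- function(X, W, b) {
  Y <- X %*% W
  sweep(Y, 2L, b, "+")
}

#' @keywords internal
#' @noRd
nnLinearBwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

## Row-wise layer norm; gamma/beta length d.
#' @keywords internal
#' @noRd
nnLayerNormFwd <- function(X, gamma, beta, eps = 1e-6) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(Y = Y, xhat = xhat, inv = inv)
}

#' @keywords internal
#' @noRd
nnLayerNormBwd <- function(dY, cache, gamma) {
  dxhat <- sweep(dY, 2L, gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  (dxhat - m1 - cache$xhat * m2) * cache$inv
}

#' @keywords internal
#' @noRd
nnSoftmaxRows <- function(X) {
  e <- exp(X - apply(X, 1L, max))
  e / rowSums(e)
}

## Weighted softmax cross-entropy; labels 1-based class indices.
## Returns mean weighted loss and dLogits for that mean.
#' @keywords internal
#' @noRd
nnSoftmaxCE <- function(logits, labels, classWeights = NULL) {
  n <- nrow(logits)
  P <- nnSoftmaxRows(logits)
  if (is.null(classWeights)) classWeights <- rep(1, ncol(logits))
  w <- classWeights[labels]
  idx <- cbind(seq_len(n), labels)
  loss <- -sum(w * log(pmax(P[idx], 1e-12))) / n
  dL <- P
  dL[idx] <- dL[idx] - 1
  dL <- dL * (w / n)
  list(loss = loss, dLogits = dL, probs = P)
}

## ---- Adam -----------------------------------------------------------------

#' @keywords internal
#' @noRd
adamInit <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

#' @keywords internal
#' @noRd
adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- 2D convolution via im2col (for the PM-extractor CNN) ----------------

#' @keywords internal
#' @noRd
nnPad2d <- function(X, p) {
  if (p == 0L) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  Xp[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- X
  Xp
}

#' @keywords internal
#' @noRd
nnIm2col <- function(X, k, stride, pad) {
  d <- dim(X)  # B, H, W, C
  Xp <- nnPad2d(X, pad)
  Ho <- (d[2] + 2 * pad - k) %/% stride + 1L
  Wo <- (d[3] + 2 * pad - k) %/% stride + 1L
  B <- d[1]; C <- d[4]
  cols <- matrix(0, B * Ho * Wo, k * k * C)
  o <- 0L
  for (dx in seq_len(k)) {      # offsets ordered (dy fastest within dx)
    for (dy in seq_len(k)) {
      o <- o + 1L
      ys <- dy + stride * (seq_len(Ho) - 1L)
      xs <- dx + stride * (seq_len(Wo) - 1L)
      sub <- Xp[, ys, xs, , drop = FALSE]
      cols[, seq.int((o - 1L) * C + 1L, o * C)] <-
        matrix(sub, B * Ho * Wo, C)
    }
  }
  list(cols = cols, Ho = Ho, Wo = Wo)
}

#' @keywords internal
#' @noRd
nnConv2dFwd <- function(X, W, b, k, stride, pad) {
  d <- dim(X)
  ic <- nnIm2col(X, k, stride, pad)
  Ymat <- nnLinearFwd(ic$cols, W, b)
  list(Y = array(Ymat, c(d[1], ic$Ho, ic$Wo, ncol(W))), cols = ic$cols,
       Ho = ic$Ho, Wo = ic$Wo)
}

#' @keywords internal
#' @noRd
nnConv2dBwd <- function(dY, X, W, k, stride, pad, cols) {
  d <- dim(X)
  B <- d[1]; C <- d[4]
  dYmat <- matrix(dY, B * dim(dY)[2] * dim(dY)[3], dim(dY)[4])
  dW <- crossprod(cols, dYmat)
  db <- colSums(dYmat)
  dcols <- dYmat %*% t(W)
  Ho <- dim(dY)[2]; Wo <- dim(dY)[3]
  dXp <- array(0, c(B, d[2] + 2 * pad, d[3] + 2 * pad, C))
  o <- 0L
  for (dx in seq_len(k)) {
    for (dy in seq_len(k)) {
      o <- o + 1L
      ys <- dy + stride * (seq_len(Ho) - 1L)
      xs <- dx + stride * (seq_len(Wo) - 1L)
      dXp[, ys, xs, ] <- dXp[, ys, xs, , drop = FALSE] +
        array(dcols[, seq.int((o - 1L) * C + 1L, o * C)], c(B, Ho, Wo, C))
    }
  }
  dX <- if (pad > 0) {
    dXp[, (pad + 1):(pad + d[2]), (pad + 1):(pad + d[3]), , drop = FALSE]
  } else dXp
  list(dX = dX, dW = dW, db = db)
}

## Non-overlapping average pooling.
#' @keywords internal
#' @noRd
nnAvgPoolFwd <- function(X, f) {
  d <- dim(X)
  Ho <- d[2] %/% f; Wo <- d[3] %/% f
  X6 <- array(X, c(d[1], f, Ho, f, Wo, d[4]))
  Xp <- aperm(X6, c(2, 4, 1, 3, 5, 6))       # pooling dims first
  colSums(Xp, dims = 2) / (f * f)            # -> [B, Ho, Wo, C]
}

#' @keywords internal
#' @noRd
nnAvgPoolBwd <- function(dY, f, inDim) {
  d <- inDim
  Ho <- d[2] %/% f; Wo <- d[3] %/% f
  g <- dY / (f * f)
  ## upsample by repetition
  dX5 <- array(0, c(d[1], f, Ho, f, Wo, d[4]))
  for (a in seq_len(f)) for (b in seq_len(f))
    dX5[, a, , b, , ] <- g
  array(dX5, d)
}

## ---- depth-wise 3D convolution over (T, H, W) x p channels ----------------

#' @keywords internal
#' @noRd
nnConv3dDepthwiseFwd <- function(V, Wk, b, kernel) {
  d <- dim(V)  # T, H, W, p
  kt <- kernel[1]; kh <- kernel[2]; kw <- kernel[3]
  if (any(d[1:3] < 1L))
    stop("kernel larger than padded extent: empty volume")
  pt <- (kt - 1L) %/% 2L; ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  Vp <- array(0, c(d[1] + 2 * pt, d[2] + 2 * ph, d[3] + 2 * pw, d[4]))
  Vp[pt + seq_len(d[1]), ph + seq_len(d[2]), pw + seq_len(d[3]), ] <- V
  thw <- d[1] * d[2] * d[3]
  out <- array(rep(b, each = thw), d)
  o <- 0L
  for (iw in seq_len(kw)) for (ih in seq_len(kh)) for (it in seq_len(kt)) {
    o <- o + 1L
    sub <- Vp[it + seq_len(d[1]) - 1L, ih + seq_len(d[2]) - 1L,
              iw + seq_len(d[3]) - 1L, , drop = FALSE]
    out <- out + sub * rep(Wk[, o], each = thw)
  }
  out
}

#' @keywords internal
#' @noRd
nnConv3dDepthwiseBwd <- function(dOut, V, Wk, kernel) {
  d <- dim(V)
  kt <- kernel[1]; kh <- kernel[2]; kw <- kernel[3]
  pt <- (kt - 1L) %/% 2L; ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  thw <- d[1] * d[2] * d[3]
  Vp <- array(0, c(d[1] + 2 * pt, d[2] + 2 * ph, d[3] + 2 * pw, d[4]))
  Vp[pt + seq_len(d[1]), ph + seq_len(d[2]), pw + seq_len(d[3]), ] <- V
  dVp <- Vp * 0
  dWk <- Wk * 0
  db <- colSums(matrix(dOut, thw, d[4]))
  o <- 0L
  for (iw in seq_len(kw)) for (ih in seq_len(kh)) for (it in seq_len(kt)) {
    o <- o + 1L
    ts <- it + seq_len(d[1]) - 1L
    hs <- ih + seq_len(d[2]) - 1L
    ws <- iw + seq_len(d[3]) - 1L
    sub <- Vp[ts, hs, ws, , drop = FALSE]
    dWk[, o] <- colSums(matrix(dOut * sub, thw, d[4]))
    dVp[ts, hs, ws, ] <- dVp[ts, hs, ws, , drop = FALSE] +
      dOut * rep(Wk[, o], each = thw)
  }
  dV <- dVp[pt + seq_len(d[1]), ph + seq_len(d[2]), pw + seq_len(d[3]), ,
            drop = FALSE]
  list(dV = dV, dW = dWk, db = db)
}
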