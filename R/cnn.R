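## Compact 3-layer CNN used as the desk-scale PM-extractor backbone:
## two strided 5x5/3x3 convolutions, average pooling to an 8x8 grid, and a
## linear classifier over 4 classes (upper, middle, lower, non-PM).
## The production-scale backbone slot is pluggable (any function pair with
## the same forward/backward contract); this one trains in minutes on CPU.

#' Initialise the compact PM-extractor CNN
#'
#' @param inputSize square input side in pixels; \code{inputSize / 4} must
#'   be divisible by 8 (e.g. 64, 96, 128, 256).
#' @param nClasses output classes (default 4: three PM classes + non-PM).
#' @param channels feature channels of the two convolution layers.
#' @param seed RNG seed for weight initialisation.
#' @return a list of parameters plus a \code{cfg} attribute.
#' @keywords internal
cnnInit <- function(inputSize, nClasses = 4L, channels = c(8L, 16L),
                    seed = 1L) {
  if ((inputSize %/% 4L) %% 8L != 0L)
    stop("inputSize / 4 must be divisible by 8")
  poolF <- (inputSize %/% 4L) %/% 8L
  nFeat <- 8L * 8L * channels[2]
  params <- withSeed(seed, {
    he <- function(fanIn, nr, nc) {
      matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fanIn)), nr, nc)
    }
    list(W1 = he(25, 25, channels[1]), b1 = rep(0, channels[1]),
         W2 = he(9 * channels[1], 9 * channels[1], channels[2]),
         b2 = rep(0, channels[2]),
         Wfc = he(nFeat, nFeat, nClasses) * 0.1, bfc = rep(0, nClasses))
  })
  attr(params, "cfg") <- list(inputSize = inputSize, channels = channels,
                              nClasses = nClasses, poolF = poolF)
  params
}

#' @keywords internal
#' @noRd
cnnForward <- function(X, net, wantCache = FALSE) {
  cfg <- attr(net, "cfg")
  c1 <- nnConv2dFwd(X, net$W1, net$b1, k = 5L, stride = 2L, pad = 2L)
  a1 <- pmax(c1$Y, 0)
  c2 <- nnConv2dFwd(a1, net$W2, net$b2, k = 3L, stride = 2L, pad = 1L)
  a2 <- pmax(c2$Y, 0)
  pooled <- nnAvgPoolFwd(a2, cfg$poolF)
  B <- dim(X)[1]
  feat <- matrix(pooled, B, length(pooled) / B)
  logits <- nnLinearFwd(feat, net$Wfc, net$bfc)
  if (!wantCache) return(list(logits = logits))
  list(logits = logits,
       cache = list(X = X, c1 = c1, a1 = a1, c2 = c2, a2 = a2, feat = feat))
}

#' @keywords internal
#' @noRd
cnnBackward <- function(dLogits, cache, net) {
  cfg <- attr(net, "cfg")
  fc <- nnLinearBwd(dLogits, cache$feat, net$Wfc)
  dPooled <- array(fc$dX, dim(nnAvgPoolFwd(cache$a2, cfg$poolF)))
  dA2 <- nnAvgPoolBwd(dPooled, cfg$poolF, dim(cache$a2))
  dC2 <- dA2 * (cache$c2$Y > 0)
  g2 <- nnConv2dBwd(dC2, cache$a1, net$W2, k = 3L, stride = 2L, pad = 1L,
                    cols = cache$c2$cols)
  dA1 <- g2$dX
  dC1 <- dA1 * (cache$c1$Y > 0)
  g1 <- nnConv2dBwd(dC1, cache$X, net$W1, k = 5L, stride = 2L, pad = 2L,
                    cols = cache$c1$cols)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       Wfc = fc$dW, bfc = fc$db)
}
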