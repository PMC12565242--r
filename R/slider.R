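## The adapter family and its host transformer.
##
## adapterForward implements the classic bottleneck adapter
##   X + f(X Wdown + bdown) Wup + bup
## and sliderForward the slice-level 3D variant
##   X + f(3DConv(X Wdown + bdown)) Wup + bup
## where the depth-wise 3D convolution acts on the (slices x patch grid)
## volume of the down-projected features. One Slider is inserted at the
## input of every transformer block of a frozen ViT backbone; only the
## adapters and the linear head are trained in slider mode.

#' Backbone configuration
#'
#' Composition of the (frozen) ViT backbone: patch embedding, learned
#' positional embedding over the patch grid plus class token, and
#' pre-norm transformer blocks with layer-scale vectors on both residual
#' branches. Defaults describe a ViT-B/14 at 518-pixel input.
#'
#' @param d embedding dimension (default 768).
#' @param nBlocks transformer blocks (default 12).
#' @param nHeads attention heads (default 12).
#' @param patchSize patch side in pixels (default 14).
#' @param inputSize input side in pixels (default 518).
#' @param mlpRatio MLP expansion factor (default 4).
#' @param nClasses classifier classes (default 2).
#' @return named list.
#' @export
backboneConfig <- function(d = 768L, nBlocks = 12L, nHeads = 12L,
                           patchSize = 14L, inputSize = 518L, mlpRatio = 4L,
                           nClasses = 2L) {
  if (inputSize %% patchSize != 0L) stop("inputSize must be a patch multiple")
  if (d %% nHeads != 0L) stop("d must be divisible by nHeads")
  grid <- inputSize %/% patchSize
  list(d = as.integer(d), nBlocks = as.integer(nBlocks),
       nHeads = as.integer(nHeads), patchSize = as.integer(patchSize),
       inputSize = as.integer(inputSize), mlpRatio = as.integer(mlpRatio),
       nClasses = as.integer(nClasses), grid = grid, L = grid * grid)
}

#' Desk-scale backbone for CPU experiments
#' @param inputSize input side (default 64).
#' @param ... further overrides passed to \code{\link{backboneConfig}}.
#' @return named list.
#' @export
tinyBackboneConfig <- function(inputSize = 64L, ...) {
  backboneConfig(d = 32L, nBlocks = 2L, nHeads = 4L, patchSize = 16L,
                 inputSize = inputSize, ...)
}

## ---- adapter primitives ---------------------------------------------------

#' Initialise adapter parameters
#'
#' Down-projection gets small random weights, the depth-wise convolution an
#' identity kernel (centre tap 1), and the up-projection is zero-initialised
#' (weights and bias) so the adapter is an exact identity at initialisation.
#'
#' @param d embedding dimension.
#' @param p bottleneck dimension.
#' @param kernel depth-wise 3D kernel shape.
#' @param seed RNG seed.
#' @return named list (Wd, bd, Wk, bk, Wu, bu).
#' @export
adapterInit <- function(d, p, kernel = c(3L, 1L, 1L), seed = 1L) {
  K <- prod(kernel)
  Wk <- matrix(0, p, K)
  Wk[, (K + 1L) %/% 2L] <- 1  # identity tap (odd kernels => exact centre)
  withSeed(seed, list(
    Wd = matrix(stats::rnorm(d * p, 0, sqrt(1 / d)), d, p),
    bd = rep(0, p), Wk = Wk, bk = rep(0, p),
    Wu = matrix(0, p, d), bu = rep(0, d)))
}

#' Bottleneck adapter forward pass
#'
#' \code{X + f(X Wd + bd) Wu + bu}; output shape equals input shape. With a
#' zero up-projection the output equals the input exactly.
#'
#' @param X L x d token matrix.
#' @param params adapter parameters (\code{\link{adapterInit}}).
#' @param activation activation name (default "gelu").
#' @return L x d matrix.
#' @export
adapterForward <- function(X, params, activation = "gelu") {
  if (ncol(X) != nrow(params$Wd)) stop("shape mismatch: ncol(X) != d")
  act <- nnActivation(activation)
  Z <- nnLinearFwd(X, params$Wd, params$bd)
  X + nnLinearFwd(act$f(Z), params$Wu, params$bu)
}

#' Slice-level 3D adapter (Slider) forward pass
#'
#' Down-projects T x L x d patch tokens, reshapes them to the
#' T x H x W x p volume, applies a depth-wise 3D convolution with "same"
#' zero padding across the slice axis and patch grid, then the activation
#' and the zero-initialised up-projection, and adds the residual.
#'
#' @param X numeric array T x L x d.
#' @param params adapter parameters.
#' @param config a \linkS4class{SliderConfig} (supplies kernel, grid,
#'   activation).
#' @return array T x L x d.
#' @export
sliderForward <- function(X, params, config) {
  stopifnot(is(config, "SliderConfig"))
  d <- dim(X)
  H <- config@patchGrid[1]; W <- config@patchGrid[2]
  if (d[2] != H * W) stop("L must equal H * W")
  if (d[3] != nrow(params$Wd)) stop("shape mismatch: embed dim")
  act <- nnActivation(config@activation)
  Xm <- .tlMat(X)                                    # (T*L) x d, slice-major
  Z <- nnLinearFwd(Xm, params$Wd, params$bd)
  V <- .mat2vol(Z, d[1], H, W)
  Cv <- nnConv3dDepthwiseFwd(V, params$Wk, params$bk, config@kernel)
  A <- act$f(.vol2mat(Cv))
  Y <- Xm + nnLinearFwd(A, params$Wu, params$bu)
  .matTL(Y, d[1], d[2], d[3])
}

## [T, L, d] array <-> (T*L) x d slice-major matrix
#' @keywords internal
#' @noRd
.tlMat <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(2, 1, 3)), d[1] * d[2], d[3])
}

#' @keywords internal
#' @noRd
.matTL <- function(M, T, L, d) {
  aperm(array(M, c(L, T, d)), c(2, 1, 3))
}

## (T*L) x p slice-major matrix (l row-major over H x W) <-> [T,H,W,p]
#' @keywords internal
#' @noRd
.mat2vol <- function(M, T, H, W) {
  aperm(array(M, c(W, H, T, ncol(M))), c(3, 2, 1, 4))
}

#' @keywords internal
#' @noRd
.vol2mat <- function(V) {
  d <- dim(V)
  matrix(aperm(V, c(3, 2, 1, 4)), d[1] * d[2] * d[3], d[4])
}

#' Reshape sequence tokens to the volumetric form
#'
#' Patch token l maps to grid position (row, col) with
#' \code{l = (row - 1) * W + col} (row-major); the inverse is
#' \code{volumeToTokens}. The round trip is lossless.
#'
#' @param X array T x L x p.
#' @param H,W patch-grid height and width (L = H * W).
#' @return array T x H x W x p.
#' @export
tokensToVolume <- function(X, H, W) {
  d <- dim(X)
  if (d[2] != H * W) stop("L must equal H * W")
  aperm(array(aperm(X, c(2, 1, 3)), c(W, H, d[1], d[3])), c(3, 2, 1, 4))
}

#' @rdname tokensToVolume
#' @param V array T x H x W x p.
#' @export
volumeToTokens <- function(V) {
  d <- dim(V)
  aperm(array(aperm(V, c(3, 2, 1, 4)), c(d[2] * d[3], d[1], d[4])),
        c(2, 1, 3))
}

## ---- parameter accounting -------------------------------------------------

#' Count tunable parameters for a fine-tuning regime
#'
#' Closed-form accounting over the backbone composition of
#' \code{\link{backboneConfig}} and the adapter composition (down-projection
#' with bias, depth-wise 3D convolution with bias over the bottleneck
#' channels, up-projection with bias):
#' \itemize{
#'   \item slider: nBlocks x (2 d p + p + d + p K + p) + head, K the kernel
#'     volume;
#'   \item full: the entire backbone plus head;
#'   \item partial: the last transformer block plus head;
#'   \item linear_probe: the head alone (d nClasses + nClasses).
#' }
#'
#' @param backbone a \code{\link{backboneConfig}} list.
#' @param slider a \linkS4class{SliderConfig} (required for slider mode).
#' @param mode "slider", "full", "partial" or "linear_probe".
#' @return a \linkS4class{ParamReport}.
#' @export
#' @examples
#' paramMillions(countTunableParams(backboneConfig(), SliderConfig(), "slider"))
countTunableParams <- function(backbone = backboneConfig(), slider = NULL,
                               mode = c("slider", "full", "partial",
                                        "linear_probe")) {
  mode <- match.arg(mode)
  d <- backbone$d; r <- backbone$mlpRatio
  head <- d * backbone$nClasses + backbone$nClasses
  block <- (d * 3 * d + 3 * d) +      # qkv
    (d * d + d) +                     # attention output
    (d * r * d + r * d) +             # MLP up
    (r * d * d + d) +                 # MLP down
    2 * 2 * d +                       # two layer norms
    2 * d                             # two layer-scale vectors
  breakdown <- switch(mode,
    slider = {
      if (is.null(slider)) stop("slider mode needs a SliderConfig")
      validObject(slider)
      p <- slider@embedDim %/% slider@reduction
      if (slider@embedDim %% slider@reduction != 0L)
        stop("non-integer bottleneck")
      K <- prod(slider@kernel)
      adapter <- 2 * slider@embedDim * p + (p + slider@embedDim) +
        p * K + p
      list(adapters = slider@nBlocks * adapter, head = head)
    },
    full = list(
      patch_embed = backbone$patchSize^2 * 3 * d + d,
      pos_embed = (backbone$L + 1) * d,
      class_token = d,
      blocks = backbone$nBlocks * block,
      final_norm = 2 * d,
      head = head),
    partial = list(last_block = block, head = head),
    linear_probe = list(head = head))
  breakdown <- lapply(breakdown, as.numeric)
  count <- sum(unlist(breakdown))
  new("ParamReport", mode = mode, count = count,
      millions = round(count / 1e6, 2), breakdown = breakdown)
}

## ---- model assembly -------------------------------------------------------

#' @keywords internal
#' @noRd
.backboneInit <- function(cfg, seed) {
  d <- cfg$d; r <- cfg$mlpRatio
  withSeed(seed, {
    rn <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
    params <- list(
      patchW = rn(cfg$patchSize^2 * 3, d, sqrt(1 / (cfg$patchSize^2 * 3))),
      patchB = rep(0, d),
      pos = rn(cfg$L + 1, d, 0.02),
      cls = stats::rnorm(d, 0, 0.02))
    for (i in seq_len(cfg$nBlocks)) {
      params[[sprintf("b%d_ln1g", i)]] <- rep(1, d)
      params[[sprintf("b%d_ln1b", i)]] <- rep(0, d)
      params[[sprintf("b%d_Wqkv", i)]] <- rn(d, 3 * d, sqrt(1 / d))
      params[[sprintf("b%d_bqkv", i)]] <- rep(0, 3 * d)
      params[[sprintf("b%d_Wo", i)]] <- rn(d, d, sqrt(1 / d))
      params[[sprintf("b%d_bo", i)]] <- rep(0, d)
      params[[sprintf("b%d_ls1", i)]] <- rep(0.5, d)
      params[[sprintf("b%d_ln2g", i)]] <- rep(1, d)
      params[[sprintf("b%d_ln2b", i)]] <- rep(0, d)
      params[[sprintf("b%d_Wm1", i)]] <- rn(d, r * d, sqrt(1 / d))
      params[[sprintf("b%d_bm1", i)]] <- rep(0, r * d)
      params[[sprintf("b%d_Wm2", i)]] <- rn(r * d, d, sqrt(1 / (r * d)))
      params[[sprintf("b%d_bm2", i)]] <- rep(0, d)
      params[[sprintf("b%d_ls2", i)]] <- rep(0.5, d)
    }
    params$lnFg <- rep(1, d)
    params$lnFb <- rep(0, d)
    params$headW <- rn(d, cfg$nClasses, 0.01)
    params$headB <- rep(0, cfg$nClasses)
    params
  })
}

#' Assemble the case-level classifier
#'
#' Builds a ViT backbone (seeded random weights unless \code{params} is
#' supplied), inserts one Slider at the input of every block (slider mode),
#' and marks the trainable parameter set by mode: \code{slider} trains the
#' adapters and the head, \code{full} everything, \code{partial} the last
#' block and the head, \code{linear_probe} only the head. The case score is
#' a linear head on the mean over slices of the final class tokens.
#'
#' @param backbone a \code{\link{backboneConfig}} list.
#' @param slider a \linkS4class{SliderConfig}; its patch grid and block
#'   count must match the backbone.
#' @param mode fine-tuning regime.
#' @param seed initialisation seed.
#' @param params optional pre-built parameter list (e.g. from a trained
#'   model).
#' @return object of class \code{sliderModel}.
#' @export
assembleModel <- function(backbone, slider = NULL,
                          mode = c("slider", "full", "partial", "linear_probe"),
                          seed = 1L, params = NULL) {
  mode <- match.arg(mode)
  if (mode == "slider") {
    if (is.null(slider)) stop("slider mode needs a SliderConfig")
    validObject(slider)
    if (slider@embedDim != backbone$d || slider@nBlocks != backbone$nBlocks ||
        any(slider@patchGrid != backbone$grid))
      stop("SliderConfig does not match the backbone (d, nBlocks, grid)")
  }
  if (is.null(params)) params <- .backboneInit(backbone, seed)
  if (mode == "slider" && is.null(params[["b1_adWd"]])) {
    p <- slider@embedDim %/% slider@reduction
    for (i in seq_len(backbone$nBlocks)) {
      ad <- adapterInit(backbone$d, p, slider@kernel,
                        seed = childSeed(seed, paste0("adapter", i)))
      for (nm in names(ad)) params[[sprintf("b%d_ad%s", i, nm)]] <- ad[[nm]]
    }
  }
  trainable <- switch(mode,
    slider = c(grep("_ad", names(params), value = TRUE), "headW", "headB"),
    full = names(params),
    partial = c(grep(sprintf("^b%d_", backbone$nBlocks), names(params),
                     value = TRUE), "headW", "headB"),
    linear_probe = c("headW", "headB"))
  structure(list(params = params, backbone = backbone, slider = slider,
                 mode = mode, trainable = trainable, seed = seed),
            class = "sliderModel")
}

#' @export
print.sliderModel <- function(x, ...) {
  nTrain <- sum(vapply(x$params[x$trainable], length, numeric(1)))
  cat(sprintf("sliderModel [%s]: d=%d, %d blocks, %d trainable parameters\n",
              x$mode, x$backbone$d, x$backbone$nBlocks, nTrain))
  invisible(x)
}

## Patchify one case stack [T, s, s, 3] (8-bit values) into (T*L) x patchDim.
#' @keywords internal
#' @noRd
.patchify <- function(stack, cfg) {
  Tn <- dim(stack)[1]; s <- cfg$inputSize; ps <- cfg$patchSize; P <- cfg$grid
  out <- matrix(0, Tn * cfg$L, ps * ps * 3)
  for (t in seq_len(Tn)) {
    img <- array(stack[t, , , ], c(s, s, 3)) / 255
    A <- array(img, c(ps, P, ps, P, 3))          # (ri, r, ci, c, ch)
    B <- aperm(A, c(1, 3, 5, 4, 2))              # (ri, ci, ch, c, r)
    out[(t - 1) * cfg$L + seq_len(cfg$L), ] <-
      t(matrix(B, ps * ps * 3, cfg$L))           # token l = (r-1)*P + c
  }
  out
}

## Full forward pass for one case. Returns logits and (optionally) caches.
#' @keywords internal
#' @noRd
.modelForward <- function(model, stack, dropoutRate = 0, wantCache = FALSE) {
  cfg <- model$backbone; pr <- model$params
  Tn <- dim(stack)[1]; L <- cfg$L; N <- L + 1L; d <- cfg$d
  act <- nnActivation(if (!is.null(model$slider)) model$slider@activation
                      else "gelu")
  patches <- .patchify(stack, cfg)
  emb <- nnLinearFwd(patches, pr$patchW, pr$patchB)
  X <- matrix(0, Tn * N, d)
  clsRows <- (seq_len(Tn) - 1L) * N + 1L
  patchRows <- setdiff(seq_len(Tn * N), clsRows)
  X[clsRows, ] <- matrix(pr$cls + t(pr$pos[1, , drop = FALSE]),
                         Tn, d, byrow = TRUE)
  X[patchRows, ] <- emb +
    pr$pos[rep(2:(L + 1L), Tn), , drop = FALSE]
  caches <- list(patches = patches, clsRows = clsRows, patchRows = patchRows)
  blocks <- vector("list", cfg$nBlocks)
  hasAdapter <- model$mode == "slider"
  for (i in seq_len(cfg$nBlocks)) {
    bc <- list(Xin = X)
    ## Slider at the block input (patch tokens only; cls bypasses it)
    if (hasAdapter) {
      a <- model$params
      Wd <- a[[sprintf("b%d_adWd", i)]]; bd <- a[[sprintf("b%d_adbd", i)]]
      Wk <- a[[sprintf("b%d_adWk", i)]]; bk <- a[[sprintf("b%d_adbk", i)]]
      Wu <- a[[sprintf("b%d_adWu", i)]]; bu <- a[[sprintf("b%d_adbu", i)]]
      Xp <- X[patchRows, , drop = FALSE]
      Z <- nnLinearFwd(Xp, Wd, bd)
      V <- .mat2vol(Z, Tn, cfg$grid, cfg$grid)
      Cv <- nnConv3dDepthwiseFwd(V, Wk, bk, model$slider@kernel)
      Cm <- .vol2mat(Cv)
      A <- act$f(Cm)
      X[patchRows, ] <- Xp + nnLinearFwd(A, Wu, bu)
      bc$ad <- list(Xp = Xp, Z = Z, V = V, Cm = Cm, A = A)
    }
    bc$Xad <- X
    ## attention sub-block
    ln1 <- nnLayerNormFwd(X, pr[[sprintf("b%d_ln1g", i)]],
                          pr[[sprintf("b%d_ln1b", i)]])
    qkv <- nnLinearFwd(ln1$Y, pr[[sprintf("b%d_Wqkv", i)]],
                       pr[[sprintf("b%d_bqkv", i)]])
    nh <- cfg$nHeads; dh <- d %/% nh
    O <- matrix(0, Tn * N, d)
    attn <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      rows <- (t - 1L) * N + seq_len(N)
      q <- qkv[rows, 1:d, drop = FALSE]
      k <- qkv[rows, d + 1:d, drop = FALSE]
      v <- qkv[rows, 2 * d + 1:d, drop = FALSE]
      Ph <- vector("list", nh)
      for (h in seq_len(nh)) {
        cols <- (h - 1L) * dh + seq_len(dh)
        S <- (q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE])) / sqrt(dh)
        P <- nnSoftmaxRows(S)
        O[rows, cols] <- P %*% v[, cols, drop = FALSE]
        Ph[[h]] <- P
      }
      attn[[t]] <- Ph
    }
    aout <- nnLinearFwd(O, pr[[sprintf("b%d_Wo", i)]],
                        pr[[sprintf("b%d_bo", i)]])
    scaled1 <- sweep(aout, 2L, pr[[sprintf("b%d_ls1", i)]], "*")
    X1 <- X + scaled1
    ## MLP sub-block
    ln2 <- nnLayerNormFwd(X1, pr[[sprintf("b%d_ln2g", i)]],
                          pr[[sprintf("b%d_ln2b", i)]])
    H1 <- nnLinearFwd(ln2$Y, pr[[sprintf("b%d_Wm1", i)]],
                      pr[[sprintf("b%d_bm1", i)]])
    G1 <- H1 * stats::pnorm(H1)  # gelu
    H2 <- nnLinearFwd(G1, pr[[sprintf("b%d_Wm2", i)]],
                      pr[[sprintf("b%d_bm2", i)]])
    scaled2 <- sweep(H2, 2L, pr[[sprintf("b%d_ls2", i)]], "*")
    X2 <- X1 + scaled2
    bc <- c(bc, list(ln1 = ln1, qkv = qkv, O = O, attn = attn, aout = aout,
                     X1 = X1, ln2 = ln2, H1 = H1, G1 = G1, H2 = H2))
    blocks[[i]] <- bc
    X <- X2
  }
  lnF <- nnLayerNormFwd(X, pr$lnFg, pr$lnFb)
  clsOut <- lnF$Y[clsRows, , drop = FALSE]
  feat <- colMeans(clsOut)
  ## feature standardiser (fitted on the training set by trainIdentifier);
  ## identity when absent
  if (!is.null(model$featNorm)) {
    feat <- (feat - model$featNorm$center) / model$featNorm$scale
  }
  dropMask <- rep(1, d)
  if (dropoutRate > 0) {
    dropMask <- (stats::runif(d) >= dropoutRate) / (1 - dropoutRate)
    feat <- feat * dropMask
  }
  logits <- matrix(feat, 1L) %*% pr$headW + matrix(pr$headB, 1L)
  if (!wantCache) return(list(logits = logits))
  caches$blocks <- blocks
  caches$lnF <- lnF
  caches$Xfinal <- X
  caches$feat <- feat
  caches$dropMask <- dropMask
  caches$Tn <- Tn
  list(logits = logits, cache = caches)
}

## Full backward pass; returns gradients for every parameter (the caller
## selects which ones to update, so frozen weights stay bitwise unchanged).
#' @keywords internal
#' @noRd
.modelBackward <- function(model, cache, dLogits) {
  cfg <- model$backbone; pr <- model$params
  Tn <- cache$Tn; L <- cfg$L; N <- L + 1L; d <- cfg$d
  act <- nnActivation(if (!is.null(model$slider)) model$slider@activation
                      else "gelu")
  g <- list()
  dFeat <- as.numeric(pr$headW %*% t(dLogits))
  g$headW <- t(matrix(cache$feat, 1L)) %*% dLogits
  g$headB <- as.numeric(dLogits)
  dFeat <- dFeat * cache$dropMask
  if (!is.null(model$featNorm)) dFeat <- dFeat / model$featNorm$scale
  dClsOut <- matrix(dFeat / Tn, Tn, d, byrow = TRUE)
  dLnFY <- matrix(0, Tn * N, d)
  dLnFY[cache$clsRows, ] <- dClsOut
  g$lnFg <- colSums(dLnFY * cache$lnF$xhat)
  g$lnFb <- colSums(dLnFY)
  dX <- nnLayerNormBwd(dLnFY, cache$lnF, pr$lnFg)
  for (i in rev(seq_len(cfg$nBlocks))) {
    bc <- cache$blocks[[i]]
    ## MLP sub-block
    dScaled2 <- dX
    g[[sprintf("b%d_ls2", i)]] <- colSums(dScaled2 * bc$H2)
    dH2 <- sweep(dScaled2, 2L, pr[[sprintf("b%d_ls2", i)]], "*")
    lb <- nnLinearBwd(dH2, bc$G1, pr[[sprintf("b%d_Wm2", i)]])
    g[[sprintf("b%d_Wm2", i)]] <- lb$dW
    g[[sprintf("b%d_bm2", i)]] <- lb$db
    dG1 <- lb$dX
    dH1 <- dG1 * (stats::pnorm(bc$H1) + bc$H1 * stats::dnorm(bc$H1))
    lb <- nnLinearBwd(dH1, bc$ln2$Y, pr[[sprintf("b%d_Wm1", i)]])
    g[[sprintf("b%d_Wm1", i)]] <- lb$dW
    g[[sprintf("b%d_bm1", i)]] <- lb$db
    g[[sprintf("b%d_ln2g", i)]] <- colSums(lb$dX * bc$ln2$xhat)
    g[[sprintf("b%d_ln2b", i)]] <- colSums(lb$dX)
    dX1 <- dX + nnLayerNormBwd(lb$dX, bc$ln2, pr[[sprintf("b%d_ln2g", i)]])
    ## attention sub-block
    dScaled1 <- dX1
    g[[sprintf("b%d_ls1", i)]] <- colSums(dScaled1 * bc$aout)
    dAout <- sweep(dScaled1, 2L, pr[[sprintf("b%d_ls1", i)]], "*")
    lb <- nnLinearBwd(dAout, bc$O, pr[[sprintf("b%d_Wo", i)]])
    g[[sprintf("b%d_Wo", i)]] <- lb$dW
    g[[sprintf("b%d_bo", i)]] <- lb$db
    dO <- lb$dX
    nh <- cfg$nHeads; dh <- d %/% nh
    dQkv <- matrix(0, Tn * N, 3 * d)
    for (t in seq_len(Tn)) {
      rows <- (t - 1L) * N + seq_len(N)
      for (h in seq_len(nh)) {
        cols <- (h - 1L) * dh + seq_len(dh)
        P <- bc$attn[[t]][[h]]
        q <- bc$qkv[rows, cols, drop = FALSE]
        k <- bc$qkv[rows, d + cols, drop = FALSE]
        v <- bc$qkv[rows, 2 * d + cols, drop = FALSE]
        dOh <- dO[rows, cols, drop = FALSE]
        dP <- dOh %*% t(v)
        dV <- t(P) %*% dOh
        dS <- P * (dP - rowSums(dP * P))
        dS <- dS / sqrt(dh)
        dQkv[rows, cols] <- dS %*% k
        dQkv[rows, d + cols] <- t(dS) %*% q
        dQkv[rows, 2 * d + cols] <- dV
      }
    }
    lb <- nnLinearBwd(dQkv, bc$ln1$Y, pr[[sprintf("b%d_Wqkv", i)]])
    g[[sprintf("b%d_Wqkv", i)]] <- lb$dW
    g[[sprintf("b%d_bqkv", i)]] <- lb$db
    g[[sprintf("b%d_ln1g", i)]] <- colSums(lb$dX * bc$ln1$xhat)
    g[[sprintf("b%d_ln1b", i)]] <- colSums(lb$dX)
    dXad <- dX1 + nnLayerNormBwd(lb$dX, bc$ln1, pr[[sprintf("b%d_ln1g", i)]])
    ## Slider at block input
    if (model$mode == "slider") {
      ad <- bc$ad
      Wd <- pr[[sprintf("b%d_adWd", i)]]
      Wk <- pr[[sprintf("b%d_adWk", i)]]
      Wu <- pr[[sprintf("b%d_adWu", i)]]
      dXp <- dXad[cache$patchRows, , drop = FALSE]
      lb <- nnLinearBwd(dXp, ad$A, Wu)
      g[[sprintf("b%d_adWu", i)]] <- lb$dW
      g[[sprintf("b%d_adbu", i)]] <- lb$db
      dA <- lb$dX
      dCm <- dA * act$df(ad$Cm)
      cb <- nnConv3dDepthwiseBwd(.mat2vol(dCm, Tn, cfg$grid, cfg$grid),
                                 ad$V, Wk, model$slider@kernel)
      g[[sprintf("b%d_adWk", i)]] <- cb$dW
      g[[sprintf("b%d_adbk", i)]] <- cb$db
      dZ <- .vol2mat(cb$dV)
      lb <- nnLinearBwd(dZ, ad$Xp, Wd)
      g[[sprintf("b%d_adWd", i)]] <- lb$dW
      g[[sprintf("b%d_adbd", i)]] <- lb$db
      dXin <- dXad
      dXin[cache$patchRows, ] <- dXin[cache$patchRows, ] + lb$dX
      dX <- dXin
    } else {
      dX <- dXad
    }
  }
  ## embedding gradients
  dPatchTok <- dX[cache$patchRows, , drop = FALSE]
  dClsTok <- dX[cache$clsRows, , drop = FALSE]
  g$cls <- colSums(dClsTok)
  dPos <- matrix(0, L + 1L, d)
  dPos[1, ] <- colSums(dClsTok)
  posIdx <- rep(2:(L + 1L), Tn)
  dPos[2:(L + 1L), ] <- rowsum(dPatchTok, posIdx)
  g$pos <- dPos
  lb <- nnLinearBwd(dPatchTok, cache$patches, pr$patchW)
  g$patchW <- lb$dW
  g$patchB <- lb$db
  g
}

#' Default identifier training configuration
#'
#' Production-scale defaults: batch 8, 80 epochs, Adam at 2e-4 with cosine
#' annealing, dropout 0.3 on the case feature, class weights 1:1.5
#' (non-PF-ILD : PF-ILD). Override any field for desk-scale runs.
#'
#' @param ... overrides.
#' @return named list.
#' @export
identifierTrainConfig <- function(...) {
  cfg <- list(batchSize = 8L, epochs = 80L, lr = 2e-4, cosine = TRUE,
              dropout = 0.3, classWeights = c(1, 1.5), seed = 1L)
  utils::modifyList(cfg, list(...))
}

#' Train the case-level PF-ILD identifier
#'
#' Optimises the mode's trainable parameters (adapters + head in slider
#' mode) with class-weighted cross-entropy; every frozen backbone weight is
#' left bitwise unchanged. Before the first epoch a per-dimension
#' standardiser for the pooled case feature is fitted on the training set
#' and stored in the model (applied identically at prediction time).
#' Fully seeded and deterministic; \code{epochs = 0} returns the
#' initialised model.
#'
#' @param model a \code{sliderModel} from \code{\link{assembleModel}}.
#' @param stacks list of case stacks (T x s x s x 3 arrays, see
#'   \code{\link{stackRSVolume}}).
#' @param labels binary labels (0/1), both classes present.
#' @param config see \code{\link{identifierTrainConfig}}.
#' @return the trained model with a \code{trainLog} element (epoch, loss,
#'   lr).
#' @export
trainIdentifier <- function(model, stacks, labels,
                            config = identifierTrainConfig()) {
  stopifnot(inherits(model, "sliderModel"))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (length(stacks) != length(labels)) stop("stacks/labels length mismatch")
  n <- length(stacks)
  log <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  if (config$epochs > 0) {
    ## fit the case-feature standardiser on the training set: the pooled
    ## class-token feature has near-constant per-dimension offsets that
    ## dwarf its discriminative variation, which cripples first-order
    ## optimisation of the head unless the feature is standardised
    if (is.null(model$featNorm)) {
      F0 <- t(vapply(stacks, function(s)
        .modelForward(model, s, wantCache = TRUE)$cache$feat,
        numeric(model$backbone$d)))
      model$featNorm <- list(center = colMeans(F0),
                             scale = pmax(apply(F0, 2L, stats::sd), 1e-6))
    }
    trainNames <- model$trainable
    opt <- adamInit(model$params[trainNames])
    for (ep in seq_len(config$epochs)) {
      lr <- if (isTRUE(config$cosine)) {
        config$lr * 0.5 * (1 + cos(pi * (ep - 1) / config$epochs))
      } else config$lr
      rng <- childSeed(config$seed, paste0("idepoch", ep))
      epLoss <- 0; nb <- 0L
      withSeed(rng, {
        ord <- sample.int(n)
        for (start in seq(1L, n, by = config$batchSize)) {
          idx <- ord[start:min(start + config$batchSize - 1L, n)]
          gacc <- NULL; bloss <- 0
          for (j in idx) {
            fw <- .modelForward(model, stacks[[j]],
                                dropoutRate = config$dropout,
                                wantCache = TRUE)
            ce <- nnSoftmaxCE(fw$logits, labels[j] + 1L,
                              classWeights = config$classWeights)
            gr <- .modelBackward(model, fw$cache, ce$dLogits)
            gr <- gr[trainNames]
            if (is.null(gacc)) gacc <- gr else {
              for (nm in trainNames) gacc[[nm]] <- gacc[[nm]] + gr[[nm]]
            }
            bloss <- bloss + ce$loss
          }
          for (nm in trainNames) gacc[[nm]] <- gacc[[nm]] / length(idx)
          upd <- adamStep(model$params[trainNames], gacc, opt, lr = lr)
          model$params[trainNames] <- upd$params
          opt <- upd$state
          epLoss <- epLoss + bloss / length(idx); nb <- nb + 1L
        }
      })
      log <- rbind(log, data.frame(epoch = ep, loss = epLoss / nb, lr = lr))
    }
  }
  model$trainLog <- log
  model
}

#' Predict the PF-ILD probability for one case
#'
#' Deterministic evaluation-mode forward pass (no dropout); returns the
#' positive-class softmax probability.
#'
#' @param model a \code{sliderModel}.
#' @param stack case stack T x s x s x 3; T must match the model's slice
#'   strategy.
#' @return numeric score in [0, 1].
#' @export
predictCase <- function(model, stack) {
  stopifnot(inherits(model, "sliderModel"))
  expT <- if (!is.null(model$slider)) model$slider@T else NULL
  if (!is.null(expT) && dim(stack)[1] != expT)
    stop("stack has ", dim(stack)[1], " slices; model expects ", expT)
  if (dim(stack)[2] != model$backbone$inputSize)
    stop("stack spatial size does not match the backbone input size")
  logits <- .modelForward(model, stack)$logits
  p <- nnSoftmaxRows(logits)
  as.numeric(p[1, 2])
}
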