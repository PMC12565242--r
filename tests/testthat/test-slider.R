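test_that("token/volume reshaping is row-major and lossless", {
  T <- 2L; H <- 3L; W <- 4L; p <- 5L
  set.seed(1)
  X <- array(rnorm(T * H * W * p), c(T, H * W, p))
  V <- tokensToVolume(X, H, W)
  expect_identical(dim(V), c(T, H, W, p))
  ## token l = (r-1)*W + c: token 4 of slice 1 sits at grid (1, 4),
  ## token 5 at (2, 1)
  expect_equal(V[1, 1, 4, ], X[1, 4, ])
  expect_equal(V[1, 2, 1, ], X[1, 5, ])
  expect_equal(V[2, 3, 2, ], X[2, (3 - 1) * W + 2, ])
  expect_equal(volumeToTokens(V), X)
})

test_that("adapterForward is an exact identity at zero up-projection", {
  set.seed(2)
  X <- matrix(rnorm(60 * 16), 60, 16)
  params <- adapterInit(16L, 4L, seed = 5)
  expect_identical(adapterForward(X, params), X)
  ## and not an identity once Wup is nonzero
  params$Wu[1, 1] <- 0.3
  expect_false(identical(adapterForward(X, params), X))
  expect_error(adapterForward(matrix(0, 3, 7), params), "shape")
})

test_that("sliderForward preserves shape and reduces to the bottleneck", {
  pair <- tinySliderPair(T = 3L)
  sc <- pair$sc
  d <- sc@embedDim; L <- prod(sc@patchGrid)
  set.seed(3)
  X <- array(rnorm(3 * L * d), c(3, L, d))
  params <- adapterInit(d, d %/% sc@reduction, sc@kernel, seed = 1)
  Y <- sliderForward(X, params, sc)
  expect_identical(dim(Y), dim(X))
  expect_equal(Y, X)  # zero-init up-projection -> identity
  ## depth-wise conv mixes along slices once Wup is on and the kernel
  ## has weight on the preceding-slice tap (taps are ordered t-1, t, t+1)
  params$Wu <- matrix(0.1, nrow(params$Wu), ncol(params$Wu))
  params$Wk[, 1] <- 0.5
  Y1 <- sliderForward(X, params, sc)
  X2 <- X
  X2[1, , ] <- X2[1, , ] + 1  # perturb slice 1 only
  Y2 <- sliderForward(X2, params, sc)
  ## kernel (3,1,1): slice 2 output must change, slice 3 must not
  expect_gt(max(abs(Y2[2, , ] - Y1[2, , ])), 0)
  expect_equal(Y2[3, , ], Y1[3, , ])
})

test_that("the depth-wise 3D convolution matches a naive loop", {
  set.seed(4)
  Tn <- 4L; H <- 3L; W <- 3L; p <- 2L
  kernel <- c(3L, 3L, 1L)
  V <- array(rnorm(Tn * H * W * p), c(Tn, H, W, p))
  Wk <- matrix(rnorm(p * prod(kernel)), p, prod(kernel))
  b <- rnorm(p)
  got <- ILDSlider:::nnConv3dDepthwiseFwd(V, Wk, b, kernel)
  ## naive: zero-padded depth-wise sum; offsets ordered t fastest,
  ## then h, then w (matching the implementation's weight layout)
  pt <- 1L; ph <- 1L; pw <- 0L
  Vp <- array(0, c(Tn + 2, H + 2, W, p))
  Vp[2:(Tn + 1), 2:(H + 1), , ] <- V
  want <- array(0, dim(V))
  for (o in seq_len(Tn)) for (i in seq_len(H)) for (j in seq_len(W))
    for (ch in seq_len(p)) {
      acc <- b[ch]; w <- 0L
      for (iw in 1:kernel[3]) for (ih in 1:kernel[2]) for (it in 1:kernel[1]) {
        w <- w + 1L
        acc <- acc + Vp[o + it - 1, i + ih - 1, j + iw - 1, ch] * Wk[ch, w]
      }
      want[o, i, j, ch] <- acc
    }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("countTunableParams matches hand-computed compositions", {
  bb <- backboneConfig()
  rep4 <- countTunableParams(bb, SliderConfig(reduction = 4L), "slider")
  ## per block: 2*768*192 + (192+768) + 192*3 + 192 = 296640; head 1538
  expect_identical(paramCount(rep4), 296640 * 12 + 1538)
  expect_identical(rep4@breakdown$adapters, 296640 * 12)
  expect_identical(rep4@breakdown$head, 1538)
  lp <- countTunableParams(bb, mode = "linear_probe")
  expect_identical(paramCount(lp), 768 * 2 + 2)
  ## kernel volume enters the count
  k333 <- countTunableParams(
    bb, SliderConfig(reduction = 4L, kernel = c(3L, 3L, 3L)), "slider")
  expect_identical(paramCount(k333) - paramCount(rep4),
                   12 * 192 * (27 - 3))
  ## non-integer bottleneck rejected
  expect_error(SliderConfig(reduction = 5L), "divisible")
  expect_error(countTunableParams(bb, mode = "slider"), "SliderConfig")
})

test_that("assembleModel marks the trainable set per mode", {
  pair <- tinySliderPair()
  mSl <- assembleModel(pair$bb, pair$sc, "slider", seed = 1)
  expect_true(all(grepl("_ad|head", mSl$trainable)))
  expect_identical(sum(vapply(mSl$params[mSl$trainable], length,
                              numeric(1))),
                   paramCount(countTunableParams(pair$bb, pair$sc,
                                                 "slider")))
  mPa <- assembleModel(pair$bb, mode = "partial", seed = 1)
  expect_true(all(grepl("^b2_|^head", mPa$trainable)))
  mLp <- assembleModel(pair$bb, mode = "linear_probe", seed = 1)
  expect_identical(sort(mLp$trainable), c("headB", "headW"))
  ## mismatched slider config is rejected
  badSc <- SliderConfig(embedDim = 64L, reduction = 4L,
                        nBlocks = pair$bb$nBlocks,
                        patchGrid = c(pair$bb$grid, pair$bb$grid))
  expect_error(assembleModel(pair$bb, badSc, "slider"), "match")
})

test_that("identity at initialisation: slider logits equal frozen backbone + head", {
  pair <- tinySliderPair(T = 3L)
  mSl <- assembleModel(pair$bb, pair$sc, "slider", seed = 7)
  mLp <- assembleModel(pair$bb, mode = "linear_probe", seed = 7)
  st <- randomStack(T = 3L)
  lSl <- ILDSlider:::.modelForward(mSl, st)$logits
  lLp <- ILDSlider:::.modelForward(mLp, st)$logits
  expect_lt(max(abs(lSl - lLp)), 1e-6)
})

test_that("model gradients match finite differences", {
  pair <- tinySliderPair(T = 2L)
  m <- assembleModel(pair$bb, pair$sc, "slider", seed = 3)
  ## move off the zero-init saddle so all adapter grads are nonzero
  set.seed(8)
  m$params$b1_adWu <- matrix(rnorm(length(m$params$b1_adWu), 0, 0.05),
                             nrow(m$params$b1_adWu))
  m$params$b2_adWu <- matrix(rnorm(length(m$params$b2_adWu), 0, 0.05),
                             nrow(m$params$b2_adWu))
  st <- randomStack(T = 2L, seed = 10)
  fw <- ILDSlider:::.modelForward(m, st, wantCache = TRUE)
  ce <- ILDSlider:::nnSoftmaxCE(fw$logits, 2L, c(1, 1.5))
  gr <- ILDSlider:::.modelBackward(m, fw$cache, ce$dLogits)
  eps <- 1e-5
  lossAt <- function(mm) {
    ILDSlider:::nnSoftmaxCE(ILDSlider:::.modelForward(mm, st)$logits, 2L,
                            c(1, 1.5))$loss
  }
  for (nm in c("b1_adWd", "b1_adWk", "b1_adbk", "b2_adWu", "headW")) {
    i <- min(4L, length(m$params[[nm]]))
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mq <- m; mq$params[[nm]][i] <- mq$params[[nm]][i] - eps
    fd <- (lossAt(mp) - lossAt(mq)) / (2 * eps)
    expect_equal(gr[[nm]][i], fd, tolerance = 1e-5,
                 label = paste("grad", nm))
  }
})

test_that("training updates only the trainable set (gradient masking)", {
  pair <- tinySliderPair(T = 2L)
  m0 <- assembleModel(pair$bb, pair$sc, "slider", seed = 5)
  stacks <- list(randomStack(2L, seed = 1), randomStack(2L, seed = 2),
                 randomStack(2L, seed = 3), randomStack(2L, seed = 4))
  cfg <- identifierTrainConfig(epochs = 1L, batchSize = 2L, seed = 5)
  m1 <- trainIdentifier(m0, stacks, c(0, 1, 0, 1), cfg)
  frozen <- setdiff(names(m0$params), m0$trainable)
  for (nm in frozen) {
    expect_identical(m1$params[[nm]], m0$params[[nm]])
  }
  changed <- vapply(m0$trainable, function(nm)
    max(abs(m1$params[[nm]] - m0$params[[nm]])), numeric(1))
  expect_gt(max(changed), 0)
})

test_that("trainIdentifier is deterministic and logs the cosine schedule", {
  pair <- tinySliderPair(T = 2L)
  stacks <- list(randomStack(2L, seed = 1), randomStack(2L, seed = 2),
                 randomStack(2L, seed = 3), randomStack(2L, seed = 4))
  cfg <- identifierTrainConfig(epochs = 3L, batchSize = 2L, seed = 9)
  m1 <- trainIdentifier(assembleModel(pair$bb, pair$sc, "slider", seed = 5),
                        stacks, c(0, 1, 0, 1), cfg)
  m2 <- trainIdentifier(assembleModel(pair$bb, pair$sc, "slider", seed = 5),
                        stacks, c(0, 1, 0, 1), cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$trainLog$lr,
                   cfg$lr * 0.5 * (1 + cos(pi * (0:2) / 3)))
  expect_error(trainIdentifier(assembleModel(pair$bb, pair$sc, "slider"),
                               stacks, c(0, 0, 0, 0), cfg), "both classes")
})

test_that("class weights scale per-class loss terms as stated", {
  logits <- matrix(c(0.2, -0.1, 0.4, 0.3), 2, byrow = TRUE)
  unw <- ILDSlider:::nnSoftmaxCE(logits, c(1L, 2L))
  p1 <- exp(logits[1, ]) / sum(exp(logits[1, ]))
  p2 <- exp(logits[2, ]) / sum(exp(logits[2, ]))
  expect_equal(unw$loss, mean(c(-log(p1[1]), -log(p2[2]))))
  w <- ILDSlider:::nnSoftmaxCE(logits, c(1L, 2L), classWeights = c(1, 1.5))
  expect_equal(w$loss, mean(c(1 * -log(p1[1]), 1.5 * -log(p2[2]))))
})

test_that("predictCase validates the slice count and returns a probability", {
  pair <- tinySliderPair(T = 3L)
  m <- assembleModel(pair$bb, pair$sc, "slider", seed = 2)
  st <- randomStack(T = 3L)
  p <- predictCase(m, st)
  expect_true(p >= 0 && p <= 1)
  expect_identical(p, predictCase(m, st))  # eval mode: deterministic
  expect_error(predictCase(m, randomStack(T = 4L)), "expects 3")
  expect_error(predictCase(m, randomStack(T = 3L, size = 32L)), "input size")
})
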