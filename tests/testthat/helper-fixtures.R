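## Shared, code-generated fixtures. Everything is deterministic and small;
## heavier fixtures are memoised per test session.

.fixtureEnv <- new.env(parent = emptyenv())

## A small phantom spec suited to fast tests.
tinySpec <- function(seed = 1L, fibrosisSeverity = 0, imageSize = 64L,
                     nSlices = 40L) {
  PhantomSpec(nSlices = nSlices, apicalOnset = 6L, bifurcation = 16L,
              disappearance = 34L, imageSize = imageSize,
              fibrosisSeverity = fibrosisSeverity, seed = seed)
}

## One memoised PhantomCase per (seed, severity) at 64 px.
tinyCase <- function(seed = 1L, fibrosisSeverity = 0) {
  key <- sprintf("case_%d_%g", seed, fibrosisSeverity)
  if (is.null(.fixtureEnv[[key]])) {
    .fixtureEnv[[key]] <- generatePhantomVolume(
      tinySpec(seed = seed, fibrosisSeverity = fibrosisSeverity))
  }
  .fixtureEnv[[key]]
}

## The tiny backbone + matching SliderConfig used across slider tests.
tinySliderPair <- function(T = 3L, reduction = 4L) {
  bb <- tinyBackboneConfig()
  sc <- SliderConfig(embedDim = bb$d, reduction = reduction,
                     nBlocks = bb$nBlocks, T = as.integer(T),
                     patchGrid = c(bb$grid, bb$grid))
  list(bb = bb, sc = sc)
}

## Deterministic random case stack at the tiny backbone input size.
randomStack <- function(T = 3L, size = 64L, seed = 9L) {
  set.seed(seed)
  array(runif(T * size * size * 3, 0, 255), c(T, size, size, 3))
}
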