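test_that("thresholdMetrics handles plain counts and zero denominators", {
  pred <- PredictionSet(labels = c(1, 1, 0, 0, 1),
                        scores = c(0.9, 0.4, 0.2, 0.7, 0.5))
  m <- thresholdMetrics(pred)
  expect_identical(m$confusion, c(tp = 2L, fp = 1L, tn = 1L, fn = 1L))
  expect_equal(m$accuracy, 3 / 5)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 1 / 2)
  ## all-negative predictions: precision undefined -> NA, not 0
  m2 <- thresholdMetrics(list(labels = c(1, 0), scores = c(0.1, 0.2)),
                         threshold = 0.9)
  expect_true(is.na(m2$precision))
  expect_true(is.na(m2$f1))
  ## threshold is inclusive: score == threshold counts positive
  m3 <- thresholdMetrics(list(labels = c(1, 0), scores = c(0.5, 0.4)),
                         threshold = 0.5)
  expect_identical(m3$confusion[["tp"]], 1L)
})

test_that("auroc handles ties via midranks and rejects one-class input", {
  lab <- c(1, 1, 0, 0)
  expect_equal(auroc(lab, c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auroc(lab, c(0.1, 0.2, 0.8, 0.9)), 0)
  expect_equal(auroc(lab, c(0.5, 0.5, 0.5, 0.5)), 0.5)
  ## one tie across classes: 3.5 wins of 4 pairs
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.5, 0.5, 0.1)), 3.5 / 4)
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("auprc equals hand-computed average precision", {
  ## perfect ranking
  expect_equal(auprc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  ## classic example: ranks pos, neg, pos -> AP = (1/1)*0.5 + (2/3)*0.5
  expect_equal(auprc(c(1, 0, 1), c(0.9, 0.8, 0.7)), 0.5 + 0.5 * 2 / 3)
  ## ties share one threshold step
  expect_equal(auprc(c(1, 0), c(0.5, 0.5)), 0.5)
})

test_that("DeLong test agrees with pROC on random data", {
  set.seed(77)
  for (i in 1:5) {
    lab <- c(rep(1, 15), rep(0, 20))
    a <- runif(35) + 0.5 * lab
    b <- runif(35) + 0.3 * lab
    got <- delongTest(lab, a, b)
    want <- pROC::roc.test(
      pROC::roc(lab, a, quiet = TRUE, direction = "<"),
      pROC::roc(lab, b, quiet = TRUE, direction = "<"),
      method = "delong", paired = TRUE)
    expect_equal(got$pValue, as.numeric(want$p.value), tolerance = 1e-10)
    expect_equal(got$aucA, as.numeric(pROC::auc(pROC::roc(lab, a,
      quiet = TRUE, direction = "<"))), tolerance = 1e-12)
  }
})

test_that("DeLong degenerate variance warns and returns p = 1", {
  lab <- c(1, 1, 0, 0)
  sc <- c(0.9, 0.8, 0.2, 0.1)
  expect_warning(res <- delongTest(lab, sc, sc), "degenerate")
  expect_identical(res$pValue, 1)
})

test_that("paired bootstrap CI is stratified, seeded and covers the truth", {
  set.seed(5)
  lab <- c(rep(1, 25), rep(0, 35))
  a <- runif(60) + 0.8 * lab
  b <- runif(60) + 0.2 * lab
  r1 <- pairedBootstrapDiffCI(lab, a, b, B = 400L, seed = 11)
  r2 <- pairedBootstrapDiffCI(lab, a, b, B = 400L, seed = 11)
  expect_identical(r1$replicates, r2$replicates)
  expect_equal(r1$diff, auroc(lab, a) - auroc(lab, b))
  expect_lt(r1$lower, r1$diff)
  expect_gt(r1$upper, r1$diff)
  ## stratification keeps every replicate defined (both classes present)
  expect_true(all(is.finite(r1$replicates)))
  ## identical models: CI contains 0
  r0 <- pairedBootstrapDiffCI(lab, a, a, B = 200L, seed = 3)
  expect_identical(r0$diff, 0)
  expect_true(r0$lower <= 0 && r0$upper >= 0)
})

test_that("permutation test switches to exhaustive enumeration", {
  set.seed(6)
  lab <- c(1, 1, 1, 0, 0, 0, 1, 0)
  a <- runif(8) + 0.6 * lab
  b <- runif(8)
  res <- auprcPermutationTest(lab, a, b, nPerm = 2^8)
  expect_true(res$exact)
  expect_identical(res$nPerm, 256L)
  ## symmetric null: swapping all scores gives the negated statistic,
  ## so the exact p of |diff| >= |obs| counts both signs
  resMC <- auprcPermutationTest(lab, a, b, nPerm = 200L, seed = 2)
  expect_false(resMC$exact)
  expect_true(resMC$pValue >= 1 / 201 && resMC$pValue <= 1)
})

test_that("evaluatePredictions bundles all metrics", {
  pred <- PredictionSet(labels = c(1, 1, 0, 0, 1, 0),
                        scores = c(0.8, 0.7, 0.3, 0.4, 0.9, 0.1))
  m <- evaluatePredictions(pred)
  expect_equal(m$auroc, 1)
  expect_equal(m$auprc, 1)
  expect_equal(m$accuracy, 1)
})
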